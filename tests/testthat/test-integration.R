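# small study-shaped dataset shared across the integration tests
make_run_input <- function(seed = 101L, p = 15L, n_rep = 6L,
                           stages = c("hESC", "EB", "Rosette", "hNPC",
                                      "Neuron")) {
  truth <- synthetic_truth(p = p, stages = stages, density = 0.08, seed = seed)
  truth <- plant_markers(truth, 1L, c("met_02", "met_05"), shift = 2.5)
  d <- generate_dataset(truth, n_rep = n_rep, seed = seed + 1L)
  list(truth = truth, data = d)
}

test_that("a k-stage run yields k - 1 transitions sharing one background", {
  inp <- make_run_input()
  cfg <- stagenet_config(cv_rounds = 2L, cv_points = 3L, seed = 3L)
  run <- run_all_transitions(inp$data, inp$truth$stages, cfg)
  expect_length(run$transitions, 4L)
  expect_identical(names(run$transitions)[1L], "hESC->EB")
  hashes <- vapply(run$transitions, function(tr) {
    paste(capture.output(str(tr$background_edges)), collapse = "")
  }, character(1))
  for (tr in run$transitions) {
    expect_identical(tr$background_edges, run$fit$full_network$edges)
  }
  expect_length(unique(hashes), 1L)

  two <- make_run_input(seed = 7L, stages = c("A", "B"))
  run2 <- run_all_transitions(two$data, two$truth$stages,
                              stagenet_config(cv_rounds = 1L, cv_points = 3L))
  expect_length(run2$transitions, 1L)
})

test_that("every metabolite gets node attributes, connected or not", {
  inp <- make_run_input()
  cfg <- stagenet_config(cv_rounds = 1L, cv_points = 2L)
  run <- run_all_transitions(inp$data, inp$truth$stages, cfg)
  tr <- run$transitions[[1L]]
  expect_setequal(tr$node_attrs$metabolite, inp$data$metabolite_names)
  expect_true(all(tr$node_attrs$score_intensity >= 0 &
                    tr$node_attrs$score_intensity <= 1))
  expect_equal(max(tr$node_attrs$score_intensity), 1)
  expect_equal(tr$node_attrs$delta_magnitude, abs(tr$node_attrs$delta))
  expect_true(all(tr$node_attrs$delta_sign %in% c(-1, 0, 1)))
  # intensity is |feature_score| max-normalized over the pair
  expect_equal(tr$node_attrs$score_intensity,
               abs(tr$node_attrs$feature_score) /
                 max(abs(tr$node_attrs$feature_score)))
})

test_that("swapping the pair flips signs and stages, preserves magnitudes", {
  inp <- make_run_input(seed = 55L)
  cfg <- stagenet_config(allow_nonconsecutive = TRUE, cv_rounds = 1L,
                         cv_points = 2L)
  fit <- stagenet_full(inp$data, inp$truth$stages, cfg)
  ab <- stagenet_transition(inp$data, c("hESC", "EB"), fit$full_network,
                            cfg, fit = fit)
  ba <- stagenet_transition(inp$data, c("EB", "hESC"), fit$full_network,
                            cfg, fit = fit)
  expect_equal(ba$node_attrs$delta, -ab$node_attrs$delta, tolerance = 1e-12)
  expect_equal(ba$node_attrs$delta_magnitude, ab$node_attrs$delta_magnitude)
  expect_equal(ba$node_attrs$score_intensity, ab$node_attrs$score_intensity,
               tolerance = 1e-10)
  # the metabolite-to-stage association is a property of the biology, not of
  # the pair ordering: orientation re-flips, so assignments are unchanged
  nz <- ab$node_attrs$feature_score != 0
  expect_identical(ab$node_attrs$assigned_stage[nz],
                   ba$node_attrs$assigned_stage[nz])
})

test_that("non-consecutive pairs are rejected unless explicitly allowed", {
  inp <- make_run_input(seed = 77L)
  cfg <- stagenet_config(cv_rounds = 1L, cv_points = 2L)
  fit <- stagenet_full(inp$data, inp$truth$stages, cfg)
  expect_error(
    stagenet_transition(inp$data, c("hESC", "Neuron"), fit$full_network,
                        cfg, fit = fit),
    "not a consecutive")
  cfg2 <- stagenet_config(allow_nonconsecutive = TRUE, cv_rounds = 1L,
                          cv_points = 2L)
  an <- stagenet_transition(inp$data, c("hESC", "Neuron"), fit$full_network,
                            cfg2, fit = fit)
  expect_s3_class(an, "AnnotatedNetwork")
})

test_that("permuting metabolite columns permutes the network labels only", {
  inp <- make_run_input(seed = 13L, p = 10L)
  cfg <- stagenet_config(cv_rounds = 2L, cv_points = 3L, seed = 2L,
                         tol = 1e-8)
  run1 <- run_all_transitions(inp$data, inp$truth$stages, cfg)

  set.seed(99)
  perm <- sample(ncol(inp$data$values))
  d2 <- concentration_matrix(inp$data$values[, perm],
                             inp$data$stage_labels, inp$data$replicate_ids,
                             metabolite_names = inp$data$metabolite_names[perm])
  run2 <- run_all_transitions(d2, inp$truth$stages, cfg)

  canon <- function(edges) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    o <- order(a, b)
    data.frame(a = a[o], b = b[o], w = edges$partial_correlation[o])
  }
  expect_equal(canon(run1$fit$full_network$edges),
               canon(run2$fit$full_network$edges), tolerance = 1e-4)
})

test_that("a transition over exchangeable stages shows only noise", {
  # two stages drawn from the same distribution: deltas are pure noise with
  # standard error sqrt(2/n_rep) on the normalized scale
  truth <- synthetic_truth(p = 10L, stages = c("A", "B"), density = 0.1,
                           seed = 61L)
  d <- generate_dataset(truth, n_rep = 50L, seed = 62L)
  cfg <- stagenet_config(cv_rounds = 1L, cv_points = 2L)
  fit <- stagenet_full(d, truth$stages, cfg)
  an <- stagenet_transition(d, c("A", "B"), fit$full_network, cfg, fit = fit)
  expect_lt(max(an$node_attrs$delta_magnitude), 3 / sqrt(50))
})

test_that("a huge transition penalty empties the transition layer", {
  inp <- make_run_input(seed = 88L)
  cfg <- stagenet_config(transition_alpha = 50, cv_rounds = 1L, cv_points = 2L)
  fit <- stagenet_full(inp$data, inp$truth$stages, cfg)
  an <- stagenet_transition(inp$data, c("hESC", "EB"), fit$full_network,
                            cfg, fit = fit)
  expect_equal(nrow(an$transition_edges), 0L)
  expect_length(an$transition_nodes, 0L)
})

test_that("planted markers dominate the overlay and keep their partners' edges", {
  passes <- 0L
  for (seed in 1:5) {
    truth <- synthetic_truth(p = 20L, density = 0.08, seed = seed + 200L)
    mk <- c("met_04", "met_11", "met_17")
    truth <- plant_markers(truth, 2L, mk, shift = 3)
    d <- generate_dataset(truth, n_rep = 50L, seed = seed + 300L)
    cfg <- stagenet_config(cv_rounds = 1L, cv_points = 2L, seed = seed)
    fit <- stagenet_full(d, truth$stages, cfg)
    an <- stagenet_transition(d, c("EB", "Rosette"), fit$full_network, cfg,
                              fit = fit)
    top <- an$node_attrs$metabolite[order(-an$node_attrs$score_intensity)][1:3]
    passes <- passes + all(mk %in% top)
    expect_identical(unique(an$node_attrs$assigned_stage[
      match(mk, an$node_attrs$metabolite)]), "Rosette")
  }
  expect_gte(passes, 4L)
})
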