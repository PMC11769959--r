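metabolite,class
alanine,amino acid
arginine,amino acid
asparagine,amino acid
aspartate,amino acid
cysteine,amino acid
glutamate,amino acid
glutamine,amino acid
glycine,amino acid
histidine,amino acid
isoleucine,amino acid
leucine,amino acid
lysine,amino acid
methionine,amino acid
phenylalanine,amino acid
proline,amino acid
serine,amino acid
threonine,amino acid
tryptophan,amino acid
tyrosine,amino acid
valine,amino acid
4-aminobutyrate,amino acid
taurine,amino acid
ATP,bioenergetics
ADP,bioenergetics
AMP,bioenergetics
NAD+,bioenergetics
NADH,bioenergetics
NADP+,bioenergetics
creatine,bioenergetics
phosphocreatine,bioenergetics
lactate,bioenergetics
pyruvate,bioenergetics
succinate,bioenergetics
fumarate,bioenergetics
malate,bioenergetics
citrate,bioenergetics
2-phosphoglycerate,bioenergetics
3-phosphoglycerate,bioenergetics
glutathione,peptide
oxidized glutathione,peptide
carnosine,peptide
anserine,peptide
homocarnosine,peptide
gamma-glutamylcysteine,peptide
glycylproline,peptide
alanylglutamine,peptide
glycylglycine,peptide
leucylalanine,peptide
seryltyrosine,peptide
aspartylphenylalanine,peptide
glycylleucine,peptide
valylvaline,peptide
prolylglycine,peptide
threonylserine,peptide
glucose,carbohydrate
fructose,carbohydrate
galactose,carbohydrate
mannose,carbohydrate
myo-inositol,carbohydrate
ribose,carbohydrate
glucose-6-phosphate,carbohydrate
fructose-6-phosphate,carbohydrate
UDP-glucose,carbohydrate
sucrose,carbohydrate
adenosine,nucleotide
guanosine,nucleotide
uridine,nucleotide
cytidine,nucleotide
inosine,nucleotide
uracil,nucleotide
hypoxanthine,nucleotide
xanthine,nucleotide
formate,organic acid
acetate,organic acid
propionate,organic acid
3-hydroxybutyrate,organic acid
2-hydroxyglutarate,organic acid
oxaloacetate,organic acid
acetoacetate,organic acid
choline,amine
phosphocholine,amine
glycerophosphocholine,amine
ethanolamine,amine
dimethylamine,amine
glycerol,lipid
sn-glycerol-3-phosphate,lipid
phosphorylethanolamine,lipid
carnitine,lipid
unidentified_1,unknown
unidentified_2,unknown
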