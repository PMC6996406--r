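# reference_total: 21324
# input_size: 128
# PANTHER Protein Class counts for a 128-protein Sus scrofa input list
# against the 21324-protein reference proteome (protein-class annotation
# dataset). reference_count = proteins of the class in the reference
# list; observed = input proteins falling in the class.
class_id	class_name	reference_count	observed
PC00228	Tubulin	20	4
PC00120	Hydratase	16	3
PC00202	Ribosomal protein	241	23
PC00092	Dehydrogenase	234	11
PC00135	Isomerase	131	6
PC00031	RNA binding protein	681	24
PC00176	Oxidoreductase	540	19
PC00041	Actin family cytoskeletal protein	313	10
PC00085	Cytoskeletal protein	660	15
PC00171	Nucleic acid binding	2031	28
UNCLASSIFIED	Unclassified	11800	31
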