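species	total	extended
Mus musculus	409098	25209
Homo sapiens	219258	9042
Saccharomyces cerevisiae	53750	2713
Schizosaccharomyces pombe	29049	1902
Caenorhabditis elegans	27488	1102
Arabidopsis thaliana	101936	503
Rattus norvegicus	72280	477
Escherichia coli	11658	426
Dictyostelium discoideum	19278	228
Drosophila melanogaster	109886	214
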