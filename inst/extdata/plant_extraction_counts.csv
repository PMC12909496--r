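species,total_genes,n_upstream,n_downstream
Berberis vulgaris,24255,24252,24255
Brassica oleracea,35400,35400,35400
Cicer anatolicum,28269,25552,25583
Glycine soja,61806,61804,61806
Oryza sativa,52424,49416,49416
Phaseolus acutifolius,50635,50220,50218
Spinacia oleracea,34876,34862,34876
Sorghum bicolor,49348,45203,45203
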