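gene_symbol
4933426M11Rik
Maf
Ccl4
Prdx1
Cdkn1a
Spp1
Cxcl2
Ywhaz
Lass6
B2m
Pfkfb3
Cd44
Sdc4
Cmpk2
Trim30a
Il1rn
Actb
Marcks
Ccl9
Ptgs2
Cebpb
Tnf
Fth1
Zeb2
Lipg
Ccl3
Pim1
Cd47
Sod2
Cxcl10
Txnrd1
Irg1
Arl8a
Nfkbia
Cd274
Rsad2
Cflar
Tor1aip1
Hmox1
Zfp36
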