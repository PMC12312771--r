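"level","block","row","ATT","SN","PBC","INT","BEH"
"within","B","ATT",0,0,0,0,0
"within","B","SN",0,0,0,0,0
"within","B","PBC",0,0,0,0,0
"within","B","INT",0.43,0.16,0.31,0,0
"within","B","BEH",0,0,0.53,0.07,0
"within","Psi","ATT",0.99,0.35,0.4,0,0
"within","Psi","SN",0.35,0.99,0.32,0,0
"within","Psi","PBC",0.4,0.32,0.99,0,0
"within","Psi","INT",0,0,0,0.5,0
"within","Psi","BEH",0,0,0,0,0.68
"within","Sigma","ATT",0.99,0.35,0.4,0.61,0.25
"within","Sigma","SN",0.35,0.99,0.32,0.41,0.2
"within","Sigma","PBC",0.4,0.32,0.99,0.53,0.56
"within","Sigma","INT",0.61,0.41,0.53,0.99,0.35
"within","Sigma","BEH",0.25,0.2,0.56,0.35,1
"between","B","ATT",0,0,0,0,0
"between","B","SN",0,0,0,0,0
"between","B","PBC",0,0,0,0,0
"between","B","INT",-0.01,0.77,0.06,0,0
"between","B","BEH",0,0,0.02,0.59,0
"between","Psi","ATT",0.05,0.04,0.01,0,0
"between","Psi","SN",0.04,0.05,0.02,0,0
"between","Psi","PBC",0.01,0.02,0.05,0,0
"between","Psi","INT",0,0,0,0.02,0
"between","Psi","BEH",0,0,0,0,0.03
"between","Sigma","ATT",0.05,0.04,0.01,0.03,0.02
"between","Sigma","SN",0.04,0.05,0.02,0.04,0.02
"between","Sigma","PBC",0.01,0.02,0.05,0.02,0.01
"between","Sigma","INT",0.03,0.04,0.02,0.05,0.03
"between","Sigma","BEH",0.02,0.02,0.01,0.03,0.05
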