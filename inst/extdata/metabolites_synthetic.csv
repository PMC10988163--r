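"name","molecular_weight","kegg","chebi","amount_value","amount_min","amount_max","original_unit","material","method","localisation","reference","isomer_group"
"metabolite_001",451.49,"C00001","CHEBI:10001",0.0912228751622186,,,"nmol_per_gLFW","whole leaf","synthetic draw","peroxisome","synthetic",
"metabolite_002",98.76,"C00002","CHEBI:10002",1.25437156698701,,,"nmol_per_gLDW","whole leaf","synthetic draw","thylakoid_lumen","synthetic",
"metabolite_003",202.44,"C00003","CHEBI:10003",0.00015247559118961,,,"nmol_per_leaf","whole leaf","synthetic draw","Golgi","synthetic",
"metabolite_004",266.26,"C00004","CHEBI:10004",0.905246319226774,0.724197055381419,1.08629558307213,"umol_per_m2_leaf","whole leaf","synthetic draw","mitochondrial_matrix;apoplast","synthetic",
"metabolite_005",147.9,"C00005","CHEBI:10005",0.0363980614265595,,,"nmol_per_gLDW","whole leaf","synthetic draw","","synthetic",
"metabolite_006",322.37,"C00006","CHEBI:10006",465.298805416846,,,"nmol_per_gLDW","whole leaf","synthetic draw","vacuole","synthetic",
"metabolite_007",315.54,"C00007","CHEBI:10007",20.6518397400327,,,"umol_per_m2_leaf","whole leaf","synthetic draw","peroxisome;vacuole;ER","synthetic",
"metabolite_008",331.58,"C00008","CHEBI:10008",25.2683034681349,,,"nmol_per_gLDW","whole leaf","synthetic draw","cytosol","synthetic",
"metabolite_009",404.2,"C00009","CHEBI:10009",0.555218190296776,0.444174552237421,0.666261828356131,"nmol_per_gLFW","whole leaf","synthetic draw","ER;mitochondrial_matrix","synthetic",
"metabolite_010",173.78,"C00010","CHEBI:10010",0.418597875928044,,,"nmol_per_mgchl","whole leaf","synthetic draw","Golgi;cytosol","synthetic",
"metabolite_011",196.13,"C00011","CHEBI:10011",1.57296575947349,1.2583726075788,1.88755891136819,"nmol_per_mgchl","whole leaf","synthetic draw","","synthetic",
"metabolite_012",94.29,"C00012","CHEBI:10012",0.0476016043712916,,,"nmol_per_mgchl","whole leaf","synthetic draw","Golgi;nucleus","synthetic",
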