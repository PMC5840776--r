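gene_id,accession,gene_class,zscore,category
RHOC,NM_175744,GTPase,-1.2576,impaired
RHOH,NM_004310,GTPase,-1.1161,impaired
RHOV,NM_133639,GTPase,-1.1100,impaired
RAC3,NM_005052,GTPase,1.6714,accelerated
RHOBTB1,NM_014836,GTPase,1.2813,accelerated
RHOQ,NM_012249,GTPase,1.1527,accelerated
ARAP1,NM_015242,GAP,-1.3971,impaired
SRGAP3,NM_014850,GAP,-1.3048,impaired
DLC1,NM_006094,GAP,1.2716,accelerated
ARAP2,NM_015230,GAP,1.2509,accelerated
ARHGAP35,NM_024342,GAP,1.1569,accelerated
ARHGAP4,NM_001666,GAP,1.0155,accelerated
ARAP3,NM_022481,GAP,1.3769,hgf_accelerated
ARHGAP24,NM_031305,GAP,1.1005,hgf_accelerated
SRGAP1,NM_020762,GAP,1.0760,hgf_accelerated
DOCK5,NM_024940,GEF,-2.3762,impaired
DOCK11,NM_144658,GEF,-1.7138,impaired
DOCK6,NM_020812,GEF,-1.5419,impaired
FGD2,NM_173558,GEF,-1.4725,impaired
DOCK3,NM_004947,GEF,-1.3736,impaired
ITSN2,NM_006277,GEF,-1.2293,impaired
SOS1,NM_005633,GEF,-1.1864,impaired
DOCK2,NM_004946,GEF,-1.1098,impaired
FGD5,NM_152536,GEF,-1.0918,impaired
VAV1,NM_005428,GEF,1.6012,accelerated
ARHGEF10,NM_014629,GEF,1.1390,accelerated
PLEKHG6,NM_018173,GEF,1.1295,accelerated
ALS2,NM_020919,GEF,1.1294,accelerated
PREX2,NM_024870,GEF,1.0269,accelerated
RASGRF1,NM_002891,GEF,1.0074,accelerated
ARHGEF4,NM_015320,GEF,-1.6365,hgf_impaired
ARHGEF19,NM_153213,GEF,-1.5797,hgf_impaired
ARHGEF14,NM_024979,GEF,-1.2354,hgf_impaired
FGD4,NM_139241,GEF,1.1248,hgf_accelerated
NOXA1,NM_006647,effector,-1.4477,impaired
PIK3R2,NM_005027,effector,-1.3197,impaired
CDC42EP2,NM_006779,effector,-1.2882,impaired
PKN3,NM_013355,effector,-1.2045,impaired
PAK7,NM_020341,effector,-1.0864,impaired
SMURF1,NM_020429,effector,-1.0663,impaired
PAK2,NM_002577,effector,-1.0318,impaired
RHPN1,NM_052924,effector,1.5692,accelerated
TWF1,NM_002822,effector,1.3241,accelerated
PAK4,NM_005884,effector,1.2268,accelerated
PIK3R1,NM_181504,effector,1.1572,accelerated
MLK4,NM_032435,effector,1.0711,accelerated
PLXNB1,NM_002673,effector,1.0377,accelerated
CIT,NM_007174,effector,-1.0435,hgf_impaired
CDC42EP1,NM_007061,effector,1.4898,hgf_accelerated
BCR,NM_004327,GAP,1.1558,accelerated
RHOBTB3,NM_014899,other,-0.9751,hgf_impaired
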