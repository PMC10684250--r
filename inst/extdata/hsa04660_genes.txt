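# Target genes of hsa-miR-155-5p enriched in hsa04660 (T cell receptor
# signaling pathway), as printed in the source data compilation.
IL4
PIK3CG
SOCS6
HRAS
IL5
TNF
PIK3CB
PIK3CD
CTLA4
NFKBIA
NFKB1
CDK4
IL10
AKT1
FOS
MAPK1
IL17
JUN
MAP3K8
MAPK3
IFNG
RHOA
ZAP70
PIK3CA
CD4
PIK3R1
IL2
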