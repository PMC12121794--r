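label	region
ctx-lh-medialorbitofrontal	L-OFC
ctx-lh-lateralorbitofrontal	L-OFC
ctx-rh-medialorbitofrontal	R-OFC
ctx-rh-lateralorbitofrontal	R-OFC
ctx-lh-rostralanteriorcingulate	L-ACC
ctx-lh-caudalanteriorcingulate	L-ACC
ctx-rh-rostralanteriorcingulate	R-ACC
ctx-rh-caudalanteriorcingulate	R-ACC
Left-Amygdala	L-Amygdala
Right-Amygdala	R-Amygdala
Left-Hippocampus	L-Hippocampus
Right-Hippocampus	R-Hippocampus
ctx-lh-parahippocampal	L-PHG
ctx-rh-parahippocampal	R-PHG
ctx-lh-superiortemporal	L-Temporal
ctx-lh-middletemporal	L-Temporal
ctx-lh-inferiortemporal	L-Temporal
ctx-rh-superiortemporal	R-Temporal
ctx-lh-precentral	L-CentralCortex
ctx-lh-postcentral	L-CentralCortex
ctx-rh-precentral	R-CentralCortex
ctx-rh-postcentral	R-CentralCortex
Left-Thalamus	L-Thalamus
Right-Thalamus	R-Thalamus
Left-Putamen	L-BasalGanglia
Left-Caudate	L-BasalGanglia
Right-Putamen	R-BasalGanglia
Left-Cerebral-White-Matter	white_matter
Right-Cerebral-White-Matter	white_matter
Left-Lateral-Ventricle	ventricle
Unknown	unknown
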