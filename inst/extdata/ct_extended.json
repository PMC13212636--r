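{"terms":{"age":{"type":"spline","var":"age","knots":null,"k":3,"forced_middle":65,"scale":1},"nihss":{"type":"linear","var":"nihss","scale":1},"aspects":{"type":"linear","var":"aspects","scale":1},"occlusion":{"type":"categorical","var":"occlusion","levels":["ICA_ICAT","M1","M2"]},"collateral":{"type":"linear","var":"collateral","scale":1},"wml_volume":{"type":"linear","var":"wml_volume","scale":5},"bpf":{"type":"spline","var":"bpf","knots":null,"k":3,"forced_middle":80,"scale":1},"icac":{"type":"categorical","var":"icac","levels":["NONE","INTIMAL","MEDIAL"]}},"treatment":true,"interactions":["collateral"]}
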