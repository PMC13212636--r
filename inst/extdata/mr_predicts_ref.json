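{"terms":{"age":{"type":"spline","var":"age","knots":null,"k":3,"forced_middle":65,"scale":1},"nihss":{"type":"linear","var":"nihss","scale":1},"sbp":{"type":"spline","var":"sbp","knots":null,"k":3,"forced_middle":130,"scale":10},"iv_alteplase":{"type":"linear","var":"iv_alteplase","scale":1},"diabetes":{"type":"linear","var":"diabetes","scale":1},"glucose":{"type":"spline","var":"glucose","knots":null,"k":3,"forced_middle":120,"scale":10},"prestroke_mrs":{"type":"linear","var":"prestroke_mrs","scale":1},"onset_to_groin":{"type":"linear","var":"onset_to_groin","scale":30},"aspects":{"type":"linear","var":"aspects","scale":1},"occlusion":{"type":"categorical","var":"occlusion","levels":["ICA_ICAT","M1","M2"]},"collateral":{"type":"linear","var":"collateral","scale":1}},"treatment":true,"interactions":["collateral"]}
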