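>sp|P49789|FHIT_HUMAN Fragile histidine triad protein (147 aa)
MSFRFGQHLIKPSVVFLKTELSFALVNRKPVVPGHVLVCPLRPVERFHDLRPDEVADLFQ
TTQRVGTVVEKHFHGTSLTFSMQDGPEAGQTVKHVHVHVLPRKAGDFHRNDSIYEELQKH
DKEDFPASWRSEEEMAAEAAALRVYFQ
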