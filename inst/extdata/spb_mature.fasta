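>SPB_MATURE mature human surfactant protein B, preprotein residues 201-279
FPIPLPYCWLCRALIKRIQAMIPKGALAVAVAQVCRVVPLVAGGICQCLAERYSVILLDT
LLGRMLPQLVCRLVLRCSM
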