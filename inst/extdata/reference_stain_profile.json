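{"stain_vectors":[[0.651107825757449,0.0701017212973667],[0.701193043123407,0.991438629777043],[0.290494260722554,0.110159847753005]],"max_concentrations":[1,1]}
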