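{"slope_pct":{"LYE":4.16666666666667,"MYE":2.17391304347826,"Across":2.85714285714286},"slope_kg":{"LYE":100,"MYE":100,"Across":100},"check_mean_t_ha":{"LYE":2.4,"MYE":4.6,"Across":3.5}}
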