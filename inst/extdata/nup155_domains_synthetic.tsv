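name	start	end
beta_propeller	1	500
crescent_alpha	501	870
cterm_stack	871	1391
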