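# Molar mass of nitrogen (g mol^-1). Configurable in the few places where it
# enters a flux conversion; 14.0 and 14.0067 give identical printed results
# for the worked examples in this package.
N_MOLAR_MASS <- 14.0067
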