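compound,eps_homo,eps_lumo
TNT,-9.0,-3.5
DN6,-8.5,-3.0
DN4,-8.3,-2.8
4AD,-7.0,-2.6
2AD,-7.1,-2.8
TNB,-9.6,-3.7
NBZ,-8.1,-2.5
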