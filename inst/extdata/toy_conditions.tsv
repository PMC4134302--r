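sample	condition
control_01	control
control_02	control
control_03	control
control_04	control
control_05	control
control_06	control
control_07	control
control_08	control
control_09	control
control_10	control
control_11	control
control_12	control
control_13	control
control_14	control
control_15	control
control_16	control
control_17	control
control_18	control
control_19	control
control_20	control
disease_01	disease
disease_02	disease
disease_03	disease
disease_04	disease
disease_05	disease
disease_06	disease
disease_07	disease
disease_08	disease
disease_09	disease
disease_10	disease
disease_11	disease
disease_12	disease
disease_13	disease
disease_14	disease
disease_15	disease
disease_16	disease
disease_17	disease
disease_18	disease
disease_19	disease
disease_20	disease
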