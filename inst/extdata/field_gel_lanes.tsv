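sample_id	sizes
lane01	299
lane02	299
lane03	299
lane04	299
lane05	299
lane06	299
lane07	199
lane08	199
lane09	299
lane10	299
lane11	199
lane12	299
lane13	299
lane14	299
lane15	299
lane16	299
lane17	299
lane18	299
lane19	299
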