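logger_id,lat,lon
2100,50.66896,-120.3624
2200,50.66715,-120.3610
2400,50.66805,-120.3650
2700,50.66909,-120.3632
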