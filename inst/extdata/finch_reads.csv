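animal_id,time,logger_id,species,sex,lon,lat
041868E9A8,2015-10-01 17:38:52,2100,House Finch,F,-120.3624,50.66896
041868E9A8,2015-10-01 17:38:54,2100,House Finch,F,-120.3624,50.66896
041868E9A8,2015-10-01 17:38:56,2100,House Finch,F,-120.3624,50.66896
041868E9A8,2015-10-01 17:38:58,2100,House Finch,F,-120.3624,50.66896
041868E9A8,2015-10-01 17:39:00,2100,House Finch,F,-120.3624,50.66896
041868E9A8,2015-10-01 17:39:12,2100,House Finch,F,-120.3624,50.66896
041868E9A8,2015-10-01 17:40:53,2100,House Finch,F,-120.3624,50.66896
041868E9A8,2015-10-01 17:45:00,2700,House Finch,F,-120.3632,50.66909
041868E9A8,2015-10-01 17:45:02,2700,House Finch,F,-120.3632,50.66909
041868E9A8,2015-10-01 17:45:04,2700,House Finch,F,-120.3632,50.66909
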