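swimmer_id,stroke,lap_index,lap_time_s
sw01,freestyle,1,13.0
sw01,freestyle,2,13.5
sw01,freestyle,3,14.0
sw01,freestyle,4,14.5
sw01,freestyle,5,15.0
sw01,freestyle,6,15.3
sw01,freestyle,7,15.6
sw01,freestyle,8,15.9
sw01,freestyle,9,16.1
sw01,freestyle,10,16.3
sw01,freestyle,11,16.5
sw01,freestyle,12,16.6
sw02,breaststroke,1,16.2
sw02,breaststroke,2,16.8
sw02,breaststroke,3,17.3
sw02,breaststroke,4,17.9
sw02,breaststroke,5,18.3
sw02,breaststroke,6,18.6
sw02,breaststroke,7,18.9
sw02,breaststroke,8,19.2
sw02,breaststroke,9,19.3
sw02,breaststroke,10,19.5
sw02,breaststroke,11,19.6
sw02,breaststroke,12,19.7
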