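deployment,tagging_date,total_length_cm,girth_cm,video_duration,acc_hz,retention_h
Fish 1,2020-03-30,135.5,99.2,10:08,50,68.00
Fish 2,2020-06-10,189.0,130.5,09:58,50,70.50
Fish 3,2020-06-30,161.0,107.8,02:49,50,70.25
Fish 4,2020-07-10,139.0,94.8,10:30,200,76.00
Fish 5,2020-07-17,140.0,99.2,10:30,200,70.50
Fish 6,2020-07-29,189.0,124.4,10:00,200,56.00
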