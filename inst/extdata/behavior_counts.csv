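class,fish1,fish2,fish3,fish4,fish5,fish6,included_in_classifier
backward_swimming,1344,312,25,393,NA,57,TRUE
boom,26,136,11,10,101,31,TRUE
gulping,45,26,16,136,33,3,TRUE
burst_swimming,107,3,NA,NA,227,NA,FALSE
feeding,NA,NA,NA,58,NA,NA,FALSE
forward_swimming,5501,5631,1577,6716,26277,2313,TRUE
gliding,339,6,NA,NA,NA,NA,FALSE
hovering,20325,6750,7722,29869,7846,32663,TRUE
turning,176,285,183,22,2026,NA,TRUE
listing,58,72,6,53,157,37,TRUE
resting,6368,21648,365,5,473,82,TRUE
rolling,3,8,NA,9,39,11,FALSE
shaking,190,589,121,542,155,415,TRUE
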