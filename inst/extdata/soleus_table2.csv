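compartment,condition,volume_cm3,volume_sd,pcsa_cm2,pcsa_sd,fascicle_length_mm,fascicle_length_sd,pennation_deg,pennation_sd,curvature_per_m,curvature_sd
MA,Short,33.5,10.1,9.3,3.5,37.7,9.3,22.0,4.7,15.3,4.4
MA,Long,33.5,11.0,6.7,2.4,51.9,13.3,17.3,3.1,7.9,2.0
MA,Change,0.0,2.1,-2.6,1.8,14.2,7.3,-4.7,2.5,-7.4,3.8
LA,Short,40.4,14.4,10.9,4.1,37.7,10.4,27.1,4.1,16.1,3.9
LA,Long,37.0,13.2,8.0,2.3,45.9,9.2,18.6,1.8,7.7,1.2
LA,Change,-3.4,4.7,-3.0,2.8,8.3,3.7,-8.5,2.6,-8.4,3.1
MP,Short,146.6,29.1,41.5,8.8,36.0,7.5,38.3,7.7,19.7,4.3
MP,Long,139.4,25.1,30.7,5.1,45.9,7.5,24.5,3.7,11.4,2.5
MP,Change,-7.2,5.5,-10.9,4.2,9.9,1.3,-13.9,5.3,-8.3,3.6
LP,Short,141.7,47.4,40.1,12.5,35.7,7.9,34.9,4.3,18.6,3.2
LP,Long,139.2,50.1,29.9,7.8,46.2,10.1,24.2,2.4,10.8,2.8
LP,Change,-2.5,5.4,-10.2,5.6,10.5,3.7,-10.7,4.0,-7.8,2.4
Whole-muscle,Short,362.2,59.2,101.8,19.1,36.8,8.4,30.6,3.3,17.4,3.6
Whole-muscle,Long,349.1,57.6,75.2,8.0,47.5,8.6,21.1,1.9,9.4,1.9
Whole-muscle,Change,-13.1,9.7,-26.6,11.5,10.7,2.7,-9.4,2.6,-8.0,2.9
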