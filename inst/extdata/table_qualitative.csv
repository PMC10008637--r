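trait,pop,h,freq.1,freq.2,freq.3,freq.4,freq.5,freq.6,freq.7,freq.8,freq.9
plant_habit,LLR,0.68,17.0,76.6,6.4,,,,,,
plant_habit,CBL,0.66,11.8,78.8,9.4,,,,,,
stem_color,LLR,0.70,63.8,35.1,1.1,,,,,,
stem_color,CBL,0.68,56.5,43.5,0.0,,,,,,
stem_pubescence,LLR,0.85,8.5,72.3,16.0,3.2,,,,,
stem_pubescence,CBL,0.83,16.5,71.8,10.6,1.2,,,,,
leaf_shape,LLR,0.37,1.1,89.4,9.6,,,,,,
leaf_shape,CBL,0.49,1.2,83.5,15.3,,,,,,
leaf_color,LLR,0.34,0.0,89.4,10.6,0.0,,,,,
leaf_color,CBL,0.32,1.2,92.9,4.7,1.2,,,,,
leaf_pubescence,LLR,0.77,41.5,56.4,2.1,0.0,,,,,
leaf_pubescence,CBL,0.58,72.9,27.1,0.0,0.0,,,,,
peduncle_attitude,LLR,1.04,19.1,44.7,36.2,,,,,,
peduncle_attitude,CBL,1.07,22.4,36.5,41.2,,,,,,
corolla_color,LLR,0.26,94.7,1.1,2.1,2.1,,,,,
corolla_color,CBL,0.06,98.8,1.2,0.0,0.0,,,,,
anther_color,LLR,0.99,2.1,45.7,44.7,7.4,,,,,
anther_color,CBL,0.99,5.9,40.0,52.9,1.2,,,,,
stigma_color,LLR,0.47,87.2,7.4,5.3,,,,,,
stigma_color,CBL,0.61,81.2,11.8,7.1,,,,,,
stigma_exertion,LLR,0.65,3.2,21.3,75.5,,,,,,
stigma_exertion,CBL,0.62,1.2,24.7,74.1,,,,,,
fruit_shape,LLR,1.55,35.1,5.3,17.0,33.0,4.3,1.1,1.1,2.1,1.1
fruit_shape,CBL,1.32,44.7,2.4,31.8,4.7,14.1,2.4,0.0,0.0,0.0
fruit_color_before_maturity,LLR,1.31,3.2,1.1,3.2,22.3,50.0,19.1,1.1,,
fruit_color_before_maturity,CBL,1.30,1.2,0.0,8.2,15.3,54.1,17.6,3.5,,
fruit_color_at_maturity,LLR,0.44,2.1,2.1,89.4,6.4,,,,,
fruit_color_at_maturity,CBL,0.52,5.9,3.5,87.1,3.5,,,,,
depth_of_stalk_cavity,LLR,1.38,28.7,20.2,25.5,25.5,,,,,
depth_of_stalk_cavity,CBL,1.38,23.5,27.1,24.7,24.7,,,,,
fruit_glossiness,LLR,0.21,5.3,94.7,,,,,,,
fruit_glossiness,CBL,0.06,1.2,98.8,,,,,,,
fruit_texture_of_surface,LLR,1.06,54.3,31.9,9.6,4.3,,,,,
fruit_texture_of_surface,CBL,1.09,38.8,47.1,8.2,5.9,,,,,
fruit_shoulder_shape,LLR,1.23,13.8,51.1,19.1,16.0,,,,,
fruit_shoulder_shape,CBL,1.28,12.9,43.5,17.6,25.9,,,,,
calyx_aspect,LLR,1.01,50.0,33.0,17.0,,,,,,
calyx_aspect,CBL,0.95,57.6,28.2,14.1,,,,,,
fruit_shape_of_apex,LLR,1.04,56.4,7.4,30.9,5.3,,,,,
fruit_shape_of_apex,CBL,1.17,45.9,10.6,35.3,8.2,,,,,
fruit_navel_appendages,LLR,0.56,75.5,24.5,,,,,,,
fruit_navel_appendages,CBL,0.68,56.5,43.5,,,,,,,
fruit_spiciness,LLR,1.31,20.2,42.6,14.9,22.3,,,,,
fruit_spiciness,CBL,1.29,42.4,27.1,12.9,17.6,,,,,
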