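scan,beam_width_mm,dpi_cGycm,ctdi_w_cGy,dlp_cGycm,f0_cGy
head,20,17.48,8.73,17.48,3.68
head,34,29.72,8.75,29.72,4.68
head,46,40.21,8.75,40.20,5.32
head,60,52.45,8.75,52.44,5.96
head,72,62.94,8.75,62.93,6.44
head,84,73.43,8.74,73.42,6.82
head,98,85.66,8.75,85.65,7.20
head,110,96.15,8.74,96.14,7.49
head,124,108.39,8.73,108.38,7.74
head,136,118.88,8.72,118.86,7.99
body,22,9.38,4.26,9.37,0.84
body,38,16.20,4.26,16.19,1.17
body,52,22.16,4.26,22.15,1.44
body,66,28.13,4.27,28.12,1.67
body,80,34.10,4.27,34.08,1.88
body,96,40.92,4.26,40.90,2.08
body,110,46.88,4.27,46.86,2.27
body,124,52.85,4.26,52.82,2.39
body,138,58.82,4.26,58.79,2.55
body,154,65.64,4.25,65.60,2.65
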