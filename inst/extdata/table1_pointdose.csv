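scan,method,beam_width_mm,ctdi_w_cGy,mean_peripheral_cGy,f0_cGy
head,measured,206,8.50,8.21,8.78
head,mc,206,8.77,8.76,8.77
body,measured,206,4.21,5.32,3.09
body,mc,206,4.26,5.44,3.08
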