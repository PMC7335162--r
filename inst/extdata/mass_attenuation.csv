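# Elemental photoabsorption mass attenuation coefficients (cm^2/g), computed
# from the Cromer-Liberman anomalous scattering tabulation via
# mu/rho = 2 * r_e * lambda * f'' * N_A / A.  Coherent and incoherent
# scattering (sub-percent to few-percent of the total at these energies in a
# carbonate matrix) are not included.  Energies are the Ka emission lines of
# Ca, Mn, Zn, Sr and the 17.4 keV incident beam energy.
element,energy_keV,mu_rho_cm2_g
C,3.6917,44.9706
C,5.8988,10.5182
C,8.6389,3.1454
C,14.165,0.6370
C,17.4,0.3264
O,3.6917,112.0688
O,5.8988,27.3662
O,8.6389,8.4543
O,14.165,1.7769
O,17.4,0.9221
Ca,3.6917,142.6666
Ca,5.8988,388.6118
Ca,8.6389,137.8856
Ca,14.165,33.9062
Ca,17.4,18.6520
Mn,3.6917,264.0256
Mn,5.8988,72.2004
Mn,8.6389,221.5111
Mn,14.165,57.7006
Mn,17.4,32.3308
Zn,3.6917,463.2616
Zn,5.8988,128.6403
Zn,8.6389,44.4453
Zn,14.165,93.2382
Zn,17.4,53.3235
Sr,3.6917,883.3517
Sr,5.8988,253.5903
Sr,8.6389,89.3200
Sr,14.165,22.3201
Sr,17.4,90.3547
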