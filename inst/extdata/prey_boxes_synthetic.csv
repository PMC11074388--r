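name,d13C_min,d13C_max,d15N_min,d15N_max
antarctic_krill_synthetic,-28.5,-25.5,2.5,5.5
subantarctic_zooplankton_synthetic,-24.5,-21.5,5.0,8.0
new_zealand_shelf_synthetic,-21.0,-18.0,9.0,13.0
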