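# Desk-scale LFM configuration used by the bundled synthetic study: a
# 24 x 24-lenslet sensor patch with 5 rectified pixels per lenslet and a
# 48 x 48 x 13-voxel reconstruction grid (2.5 um lateral, 4 um axial).
lenslet_pitch_um: 125
magnification: 25
camera_pixel_um: 6.5
pixels_per_lenslet: 5
emission_wavelength_um: 0.53
mla_f_number: 10
n_lenslets_y: 24
n_lenslets_x: 24
z_step_um: 4
n_z: 13
lateral_supersampling: 2
frame_rate_hz: 100
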