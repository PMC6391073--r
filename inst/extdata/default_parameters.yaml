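# Default parameters of the coarse-grained proteome-allocation model.
# Units follow the conventions of model_parameters(); see the package
# vignette for the calibration of the effective constants.
sigma: 0.7        # nm^2; effective PSU absorption cross-section (fitted)
tau: 75           # s^-1; PSU turnover rate (fitted)
kd: 1.0e-6        # photodamage probability per damaging excitation (fitted)
damage_target: excited  # damaging excitations hit busy (excited) units
kdiff: 1.0e-6     # mmol gDW^-1 s^-1 mM^-1; passive Ci diffusion, 2 um cell
v_cell: 4.86e-4   # L gDW^-1; cell volume per dry weight
kcat_T: 100       # s^-1; bicarbonate transporter turnover
Km_T: 15          # mM; transporter half-saturation for external Ci
kcat_M: 1.1       # s^-1; effective metabolic turnover (calibrated)
Km_M: 5.0e-3      # mmol gDW^-1; half-saturation for internal Ci
kcat_R: 10        # aa s^-1; effective ribosome elongation rate (calibrated)
Km_aa: 5.0e-3     # mmol gDW^-1; translation half-saturation, amino acids
Km_e: 5.0e-3      # mmol gDW^-1; translation half-saturation, energy
m: 8.0e-4         # mmol energy gDW^-1 s^-1; maintenance drain (calibrated)
phi_Q: 0.5        # growth-independent proteome mass fraction
Dc: 3.2           # mmol aa gDW^-1; proteome density (~0.35 g protein/gDW)
n_T: 1700         # aa; transporter unit length
n_M: 2500         # aa; metabolic enzyme unit length
n_R: 7360         # aa; ribosome protein length
n_P: 15000        # aa; effective PSU unit length incl. antenna (calibrated)
n_Q: 300          # aa; growth-independent protein length
e_aa: 2           # energy equivalents per amino acid polymerized
e_t: 6.8          # energy equivalents per carbon fixed and imported
c_aa: 5           # carbon atoms per amino acid
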