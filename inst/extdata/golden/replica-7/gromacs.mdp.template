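; GROMACS run-parameter template (commented; running MD is out of scope)
; integrator  = md        ; leapfrog
; dt          = 0.002     ; 2 fs with LINCS on hydrogen stretches
; tcoupl      = V-rescale ; 298 K thermostat
; pcoupl      = C-rescale ; 1 bar barostat
; coulombtype = PME       ; rvdw = 1.0 nm
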