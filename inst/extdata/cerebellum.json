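{
  "layers": [
    {
      "layer": "molecular_upper",
      "thickness_um": 100,
      "population": "ST",
      "n_sheets": 4,
      "nx": 32,
      "ny": 32
    },
    {
      "layer": "molecular_lower",
      "thickness_um": 100,
      "population": "BA",
      "n_sheets": 1,
      "nx": 32,
      "ny": 32
    },
    {
      "layer": "pc_layer",
      "thickness_um": 30,
      "population": "PC",
      "n_sheets": 1,
      "nx": 32,
      "ny": 32
    },
    {
      "layer": "granular",
      "thickness_um": 200,
      "population": "GR",
      "n_sheets": 8,
      "nx": 320,
      "ny": 320
    },
    {
      "layer": "granular",
      "thickness_um": 200,
      "population": "GO",
      "n_sheets": 1,
      "nx": 32,
      "ny": 32
    },
    {
      "layer": "dcn",
      "thickness_um": 100,
      "population": "DCN",
      "n_sheets": 1,
      "nx": 32,
      "ny": 32
    },
    {
      "layer": "io",
      "thickness_um": 100,
      "population": "IO",
      "n_sheets": 1,
      "nx": 1,
      "ny": 1
    },
    {
      "layer": "pons",
      "thickness_um": 200,
      "population": "Pons",
      "n_sheets": 1,
      "nx": 32,
      "ny": 32
    }
  ],
  "neurons": [
    {
      "population": "ST",
      "tau_m": 10,
      "theta": -55,
      "v_reset": -70,
      "e_rest": -70,
      "i_ex": 0,
      "t_ref": 1,
      "transmitter": "inhibitory"
    },
    {
      "population": "BA",
      "tau_m": 10,
      "theta": -55,
      "v_reset": -70,
      "e_rest": -70,
      "i_ex": 0,
      "t_ref": 1,
      "transmitter": "inhibitory"
    },
    {
      "population": "PC",
      "tau_m": 10,
      "theta": -50,
      "v_reset": -70,
      "e_rest": -70,
      "i_ex": 22,
      "t_ref": 1,
      "transmitter": "inhibitory"
    },
    {
      "population": "GR",
      "tau_m": 7.2,
      "theta": -35,
      "v_reset": -70,
      "e_rest": -58,
      "i_ex": 0,
      "t_ref": 1,
      "transmitter": "excitatory"
    },
    {
      "population": "GO",
      "tau_m": 12,
      "theta": -50,
      "v_reset": -70,
      "e_rest": -70,
      "i_ex": 0,
      "t_ref": 1,
      "transmitter": "inhibitory"
    },
    {
      "population": "DCN",
      "tau_m": 10,
      "theta": -40,
      "v_reset": -70,
      "e_rest": -70,
      "i_ex": 32,
      "t_ref": 1,
      "transmitter": "excitatory"
    },
    {
      "population": "IO",
      "tau_m": 10,
      "theta": -50,
      "v_reset": -70,
      "e_rest": -70,
      "i_ex": 50,
      "t_ref": 1500,
      "transmitter": "excitatory"
    },
    {
      "population": "Pons",
      "tau_m": 10,
      "theta": -50,
      "v_reset": -70,
      "e_rest": -70,
      "i_ex": 24,
      "t_ref": 1,
      "transmitter": "excitatory"
    }
  ],
  "projections": [
    {
      "projection": "GO->GR",
      "pre": "GO",
      "post": "GR",
      "kernel": "gaussian",
      "p": 0.04,
      "sigma_um": 200,
      "cutoff_um": 600,
      "pre_width_um": null,
      "post_width_um": null
    },
    {
      "projection": "IO->PC",
      "pre": "IO",
      "post": "PC",
      "kernel": "gaussian",
      "p": 1,
      "sigma_um": 350,
      "cutoff_um": 1050,
      "pre_width_um": null,
      "post_width_um": null
    },
    {
      "projection": "Pons->GR",
      "pre": "Pons",
      "post": "GR",
      "kernel": "gaussian",
      "p": 1,
      "sigma_um": 25,
      "cutoff_um": 75,
      "pre_width_um": null,
      "post_width_um": null
    },
    {
      "projection": "ST->ST",
      "pre": "ST",
      "post": "ST",
      "kernel": "cross",
      "p": 0.02,
      "sigma_um": null,
      "cutoff_um": null,
      "pre_width_um": 50,
      "post_width_um": 200
    },
    {
      "projection": "ST->PC",
      "pre": "ST",
      "post": "PC",
      "kernel": "cross",
      "p": 0.1,
      "sigma_um": null,
      "cutoff_um": null,
      "pre_width_um": 50,
      "post_width_um": 200
    },
    {
      "projection": "BA->BA",
      "pre": "BA",
      "post": "BA",
      "kernel": "cross",
      "p": 0.02,
      "sigma_um": null,
      "cutoff_um": null,
      "pre_width_um": 50,
      "post_width_um": 200
    },
    {
      "projection": "BA->PC",
      "pre": "BA",
      "post": "PC",
      "kernel": "cross",
      "p": 0.1,
      "sigma_um": null,
      "cutoff_um": null,
      "pre_width_um": 50,
      "post_width_um": 200
    },
    {
      "projection": "PC->BA",
      "pre": "PC",
      "post": "BA",
      "kernel": "cross",
      "p": 0.05,
      "sigma_um": null,
      "cutoff_um": null,
      "pre_width_um": 50,
      "post_width_um": 200
    },
    {
      "projection": "PC->DCN",
      "pre": "PC",
      "post": "DCN",
      "kernel": "cross",
      "p": 0.3,
      "sigma_um": null,
      "cutoff_um": null,
      "pre_width_um": 75,
      "post_width_um": 600
    },
    {
      "projection": "GR->ST",
      "pre": "GR",
      "post": "ST",
      "kernel": "cross",
      "p": 0.05,
      "sigma_um": null,
      "cutoff_um": null,
      "pre_width_um": 500,
      "post_width_um": 100
    },
    {
      "projection": "GR->BA",
      "pre": "GR",
      "post": "BA",
      "kernel": "cross",
      "p": 0.05,
      "sigma_um": null,
      "cutoff_um": null,
      "pre_width_um": 500,
      "post_width_um": 100
    },
    {
      "projection": "GR->PC",
      "pre": "GR",
      "post": "PC",
      "kernel": "cross",
      "p": 0.05,
      "sigma_um": null,
      "cutoff_um": null,
      "pre_width_um": 500,
      "post_width_um": 100
    },
    {
      "projection": "GR->GO",
      "pre": "GR",
      "post": "GO",
      "kernel": "cross",
      "p": 0.025,
      "sigma_um": null,
      "cutoff_um": null,
      "pre_width_um": 250,
      "post_width_um": 100
    }
  ],
  "receptors": [
    {
      "projection": "GO->GR",
      "kind": "GABA_A",
      "tau_syn": 10,
      "e_rev": -80,
      "weight": 3
    },
    {
      "projection": "IO->PC",
      "kind": "AMPA",
      "tau_syn": 2,
      "e_rev": 0,
      "weight": 0.1
    },
    {
      "projection": "Pons->GR",
      "kind": "AMPA",
      "tau_syn": 2,
      "e_rev": 0,
      "weight": 0.5
    },
    {
      "projection": "ST->ST",
      "kind": "GABA_A",
      "tau_syn": 2,
      "e_rev": -80,
      "weight": 0.02
    },
    {
      "projection": "ST->PC",
      "kind": "GABA_A",
      "tau_syn": 2,
      "e_rev": -80,
      "weight": 0.05
    },
    {
      "projection": "BA->BA",
      "kind": "GABA_A",
      "tau_syn": 2,
      "e_rev": -80,
      "weight": 0.02
    },
    {
      "projection": "BA->PC",
      "kind": "GABA_A",
      "tau_syn": 2,
      "e_rev": -80,
      "weight": 0.1
    },
    {
      "projection": "PC->BA",
      "kind": "GABA_A",
      "tau_syn": 2,
      "e_rev": -80,
      "weight": 0.01
    },
    {
      "projection": "PC->DCN",
      "kind": "GABA_A",
      "tau_syn": 2,
      "e_rev": -80,
      "weight": 0.0025
    },
    {
      "projection": "GR->ST",
      "kind": "AMPA",
      "tau_syn": 2,
      "e_rev": 0,
      "weight": 0.00145
    },
    {
      "projection": "GR->BA",
      "kind": "AMPA",
      "tau_syn": 2,
      "e_rev": 0,
      "weight": 0.00145
    },
    {
      "projection": "GR->PC",
      "kind": "AMPA",
      "tau_syn": 2,
      "e_rev": 0,
      "weight": 0.0013
    },
    {
      "projection": "GR->GO",
      "kind": "AMPA",
      "tau_syn": 2,
      "e_rev": 0,
      "weight": 0.0008
    },
    {
      "projection": "GR->GO",
      "kind": "NMDA",
      "tau_syn": 100,
      "e_rev": 0,
      "weight": 0.00017
    }
  ],
  "drivers": [
    {
      "population": "Pons",
      "mode": "poisson_rate",
      "rate_hz": 8,
      "amplitude": null,
      "period_ms": null,
      "phase": null
    }
  ]
}
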