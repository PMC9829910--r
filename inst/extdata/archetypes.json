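{
  "comment": "Synthetic observer archetype library: the subject types the screening protocol distinguishes, with per-eye parameters. Brightness attenuation in log units; acuity components in logMAR (neural = pinhole-resistant, refractive = removed by pinhole).",
  "archetypes": [
    {
      "label": "normal",
      "brightness_attenuation": {"OD": 0, "OS": 0},
      "neural_logmar": {"OD": 0, "OS": 0},
      "refractive_logmar": {"OD": 0, "OS": 0},
      "color_axis": {"OD": "none", "OS": "none"}
    },
    {
      "label": "unilateral-amblyope",
      "comment": "untreated left amblyope: brightness deficit, pinhole-resistant acuity loss, acquired tritan defect in the amblyopic eye",
      "brightness_attenuation": {"OD": 0, "OS": 0.6},
      "neural_logmar": {"OD": 0, "OS": 0.3},
      "refractive_logmar": {"OD": 0, "OS": 0},
      "color_axis": {"OD": "none", "OS": "tritan"}
    },
    {
      "label": "unilateral-amblyope-mild",
      "brightness_attenuation": {"OD": 0, "OS": 0.3},
      "neural_logmar": {"OD": 0, "OS": 0.3},
      "refractive_logmar": {"OD": 0, "OS": 0},
      "color_axis": {"OD": "none", "OS": "none"}
    },
    {
      "label": "refractive",
      "comment": "uncorrected refractive error; acuity normalises through the pinhole",
      "brightness_attenuation": {"OD": 0, "OS": 0},
      "neural_logmar": {"OD": 0, "OS": 0},
      "refractive_logmar": {"OD": 0.3, "OS": 0.3},
      "color_axis": {"OD": "none", "OS": "none"}
    },
    {
      "label": "treated-amblyope",
      "comment": "successfully treated; normal acuity, alternating ocular preference across games",
      "brightness_attenuation": {"OD": 0, "OS": 0},
      "neural_logmar": {"OD": 0, "OS": 0},
      "refractive_logmar": {"OD": 0, "OS": 0},
      "color_axis": {"OD": "none", "OS": "none"},
      "preference_cycle": [0.3, -0.3, 0]
    },
    {
      "label": "color-defect",
      "comment": "hereditary bilateral identical red-green defect",
      "brightness_attenuation": {"OD": 0, "OS": 0},
      "neural_logmar": {"OD": 0, "OS": 0},
      "refractive_logmar": {"OD": 0, "OS": 0},
      "color_axis": {"OD": "red-green", "OS": "red-green"}
    }
  ]
}
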