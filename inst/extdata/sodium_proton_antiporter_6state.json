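{
  "states": ["1", "2", "3", "4", "5", "6"],
  "edges": [
    {
      "from": "1",
      "to": "2",
      "process": "binding",
      "ligand": "H",
      "side": "ext",
      "order": 2,
      "concentration": "c_H_ext",
      "rate": "k_1_2",
      "value": 35421.2470166316
    },
    {
      "from": "1",
      "to": "4",
      "process": "leakage",
      "ligand": null,
      "side": "none",
      "order": 1,
      "concentration": null,
      "rate": "k_1_4",
      "value": 1
    },
    {
      "from": "1",
      "to": "6",
      "process": "binding",
      "ligand": "Na",
      "side": "ext",
      "order": 2,
      "concentration": "c_Na_ext",
      "rate": "k_1_6",
      "value": 451660557
    },
    {
      "from": "2",
      "to": "1",
      "process": "unbinding",
      "ligand": "H",
      "side": "ext",
      "order": 1,
      "concentration": null,
      "rate": "k_2_1",
      "value": 1775.26768038939
    },
    {
      "from": "2",
      "to": "3",
      "process": "conformational",
      "ligand": null,
      "side": "none",
      "order": 1,
      "concentration": null,
      "rate": "k_2_3",
      "value": 69
    },
    {
      "from": "3",
      "to": "2",
      "process": "conformational",
      "ligand": null,
      "side": "none",
      "order": 1,
      "concentration": null,
      "rate": "k_3_2",
      "value": 69
    },
    {
      "from": "3",
      "to": "4",
      "process": "unbinding",
      "ligand": "H",
      "side": "int",
      "order": 1,
      "concentration": null,
      "rate": "k_3_4",
      "value": 1775.26768038939
    },
    {
      "from": "4",
      "to": "1",
      "process": "leakage",
      "ligand": null,
      "side": "none",
      "order": 1,
      "concentration": null,
      "rate": "k_4_1",
      "value": 1
    },
    {
      "from": "4",
      "to": "3",
      "process": "binding",
      "ligand": "H",
      "side": "int",
      "order": 2,
      "concentration": "c_H_int",
      "rate": "k_4_3",
      "value": 35.4212470166316
    },
    {
      "from": "4",
      "to": "5",
      "process": "binding",
      "ligand": "Na",
      "side": "int",
      "order": 2,
      "concentration": "c_Na_int",
      "rate": "k_4_5",
      "value": 30110703.8
    },
    {
      "from": "5",
      "to": "4",
      "process": "unbinding",
      "ligand": "Na",
      "side": "int",
      "order": 1,
      "concentration": null,
      "rate": "k_5_4",
      "value": 90332111.4
    },
    {
      "from": "5",
      "to": "6",
      "process": "conformational",
      "ligand": null,
      "side": "none",
      "order": 1,
      "concentration": null,
      "rate": "k_5_6",
      "value": 350
    },
    {
      "from": "6",
      "to": "1",
      "process": "unbinding",
      "ligand": "Na",
      "side": "ext",
      "order": 1,
      "concentration": null,
      "rate": "k_6_1",
      "value": 90332111.4
    },
    {
      "from": "6",
      "to": "5",
      "process": "conformational",
      "ligand": null,
      "side": "none",
      "order": 1,
      "concentration": null,
      "rate": "k_6_5",
      "value": 350
    }
  ]
}
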