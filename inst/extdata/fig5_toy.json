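{
  "id": "toy_network",
  "metabolites": [
    {
      "id": "Met_A",
      "name": "Met_A",
      "compartment": "c"
    },
    {
      "id": "Met_B",
      "name": "Met_B",
      "compartment": "c"
    },
    {
      "id": "Met_C",
      "name": "Met_C",
      "compartment": "c"
    },
    {
      "id": "Met_D",
      "name": "Met_D",
      "compartment": "c"
    },
    {
      "id": "Met_E",
      "name": "Met_E",
      "compartment": "c"
    },
    {
      "id": "Met_F",
      "name": "Met_F",
      "compartment": "c"
    },
    {
      "id": "Met_G",
      "name": "Met_G",
      "compartment": "c"
    },
    {
      "id": "Met_H",
      "name": "Met_H",
      "compartment": "c"
    },
    {
      "id": "Met_I",
      "name": "Met_I",
      "compartment": "c"
    }
  ],
  "reactions": [
    {
      "id": "R1",
      "stoich": {
        "Met_A": -1,
        "Met_B": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "reversible": false,
      "gpr": "Enz_1",
      "subsystem": "toy",
      "exchange": false
    },
    {
      "id": "R2",
      "stoich": {
        "Met_B": -1,
        "Met_C": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "reversible": false,
      "gpr": "Enz_2",
      "subsystem": "toy",
      "exchange": false
    },
    {
      "id": "R3",
      "stoich": {
        "Met_C": -1,
        "Met_G": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "reversible": false,
      "gpr": "Enz_3",
      "subsystem": "toy",
      "exchange": false
    },
    {
      "id": "R4",
      "stoich": {
        "Met_B": -1,
        "Met_D": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "reversible": false,
      "gpr": "Enz_4",
      "subsystem": "toy",
      "exchange": false
    },
    {
      "id": "R5",
      "stoich": {
        "Met_D": -1,
        "Met_H": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "reversible": false,
      "gpr": "Enz_5",
      "subsystem": "toy",
      "exchange": false
    },
    {
      "id": "R6",
      "stoich": {
        "Met_B": -1,
        "Met_E": 1,
        "Met_F": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "reversible": false,
      "gpr": "Enz_6",
      "subsystem": "toy",
      "exchange": false
    },
    {
      "id": "R7",
      "stoich": {
        "Met_E": -1,
        "Met_F": -1,
        "Met_I": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "reversible": false,
      "gpr": "Enz_7",
      "subsystem": "toy",
      "exchange": false
    },
    {
      "id": "EX_Met_A",
      "stoich": {
        "Met_A": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "reversible": false,
      "gpr": "",
      "subsystem": "exchange",
      "exchange": true
    },
    {
      "id": "EX_Met_G",
      "stoich": {
        "Met_G": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "reversible": false,
      "gpr": "",
      "subsystem": "exchange",
      "exchange": true
    },
    {
      "id": "EX_Met_H",
      "stoich": {
        "Met_H": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "reversible": false,
      "gpr": "",
      "subsystem": "exchange",
      "exchange": true
    },
    {
      "id": "EX_Met_I",
      "stoich": {
        "Met_I": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "reversible": false,
      "gpr": "",
      "subsystem": "exchange",
      "exchange": true
    }
  ]
}
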