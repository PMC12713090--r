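{
  "id": "toy_redundant",
  "metabolites": [
    {
      "id": "A",
      "name": "A",
      "compartment": "c",
      "formula": "C6H12O6"
    },
    {
      "id": "X",
      "name": "X",
      "compartment": "c",
      "formula": "C6H12O6"
    },
    {
      "id": "P",
      "name": "P",
      "compartment": "c",
      "formula": "C6H12O6"
    }
  ],
  "reactions": [
    {
      "id": "EX_a",
      "name": "EX_a",
      "mets": {
        "A": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "",
      "subsystem": ""
    },
    {
      "id": "R_direct",
      "name": "R_direct",
      "mets": {
        "A": -1,
        "P": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "",
      "subsystem": ""
    },
    {
      "id": "R_via1",
      "name": "R_via1",
      "mets": {
        "A": -1,
        "X": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "",
      "subsystem": ""
    },
    {
      "id": "R_via2",
      "name": "R_via2",
      "mets": {
        "X": -1,
        "P": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "",
      "subsystem": ""
    },
    {
      "id": "EX_p",
      "name": "EX_p",
      "mets": {
        "P": -1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "",
      "subsystem": ""
    }
  ],
  "biomass": "EX_p",
  "objective": "EX_p"
}
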