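{
  "id": "toy_linear",
  "metabolites": [
    {
      "id": "A",
      "name": "carbon pool",
      "compartment": "c",
      "formula": "C6H12O6"
    },
    {
      "id": "P",
      "name": "product",
      "compartment": "c",
      "formula": "C6H12O6"
    },
    {
      "id": "BIO",
      "name": "biomass",
      "compartment": "b",
      "boundary": true
    }
  ],
  "reactions": [
    {
      "id": "EX_glc",
      "name": "carbon uptake",
      "mets": {
        "A": 1
      },
      "lb": 0,
      "ub": 10,
      "gpr": "",
      "subsystem": ""
    },
    {
      "id": "R_bio",
      "name": "growth",
      "mets": {
        "A": -1,
        "BIO": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "",
      "subsystem": ""
    },
    {
      "id": "R_p",
      "name": "product branch",
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
      "id": "EX_p",
      "name": "product exchange",
      "mets": {
        "P": -1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "",
      "subsystem": ""
    }
  ],
  "biomass": "R_bio",
  "objective": "R_bio"
}
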