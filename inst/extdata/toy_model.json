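{
  "metabolites": [
    {
      "id": "m_1_0",
      "name": "m_1_0",
      "compartment": "c"
    },
    {
      "id": "m_1_1",
      "name": "m_1_1",
      "compartment": "c"
    },
    {
      "id": "m_1_2",
      "name": "m_1_2",
      "compartment": "c"
    },
    {
      "id": "m_1_3",
      "name": "m_1_3",
      "compartment": "c"
    },
    {
      "id": "m_1_4",
      "name": "m_1_4",
      "compartment": "c"
    },
    {
      "id": "m_2_0",
      "name": "m_2_0",
      "compartment": "c"
    },
    {
      "id": "m_2_1",
      "name": "m_2_1",
      "compartment": "c"
    },
    {
      "id": "m_2_2",
      "name": "m_2_2",
      "compartment": "c"
    },
    {
      "id": "m_2_3",
      "name": "m_2_3",
      "compartment": "c"
    },
    {
      "id": "m_2_4",
      "name": "m_2_4",
      "compartment": "c"
    },
    {
      "id": "m_3_0",
      "name": "m_3_0",
      "compartment": "c"
    },
    {
      "id": "m_3_1",
      "name": "m_3_1",
      "compartment": "c"
    },
    {
      "id": "m_3_2",
      "name": "m_3_2",
      "compartment": "c"
    },
    {
      "id": "m_3_3",
      "name": "m_3_3",
      "compartment": "c"
    },
    {
      "id": "m_3_4",
      "name": "m_3_4",
      "compartment": "c"
    },
    {
      "id": "m_4_0",
      "name": "m_4_0",
      "compartment": "c"
    },
    {
      "id": "m_4_1",
      "name": "m_4_1",
      "compartment": "c"
    },
    {
      "id": "m_4_2",
      "name": "m_4_2",
      "compartment": "c"
    },
    {
      "id": "m_4_3",
      "name": "m_4_3",
      "compartment": "c"
    },
    {
      "id": "m_4_4",
      "name": "m_4_4",
      "compartment": "c"
    }
  ],
  "reactions": [
    {
      "id": "EX_in_P1",
      "mets": {
        "m_1_0": -1
      },
      "lb": -1000,
      "ub": 1000,
      "gpr": "",
      "pathway": "P1",
      "exchange": true
    },
    {
      "id": "R_1_1",
      "mets": {
        "m_1_0": -1,
        "m_1_1": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_1_1",
      "pathway": "P1",
      "exchange": false
    },
    {
      "id": "R_1_2",
      "mets": {
        "m_1_1": -1,
        "m_1_2": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_1_2",
      "pathway": "P1",
      "exchange": false
    },
    {
      "id": "R_1_3",
      "mets": {
        "m_1_2": -1,
        "m_1_3": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_1_3",
      "pathway": "P1",
      "exchange": false
    },
    {
      "id": "R_1_4",
      "mets": {
        "m_1_3": -1,
        "m_1_4": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_1_4",
      "pathway": "P1",
      "exchange": false
    },
    {
      "id": "EX_out_P1",
      "mets": {
        "m_1_4": -1
      },
      "lb": -1000,
      "ub": 1000,
      "gpr": "",
      "pathway": "P1",
      "exchange": true
    },
    {
      "id": "EX_in_P2",
      "mets": {
        "m_2_0": -1
      },
      "lb": -1000,
      "ub": 1000,
      "gpr": "",
      "pathway": "P2",
      "exchange": true
    },
    {
      "id": "R_2_1",
      "mets": {
        "m_2_0": -1,
        "m_2_1": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "(g_R_2_1a and g_R_2_1b)",
      "pathway": "P2",
      "exchange": false
    },
    {
      "id": "R_2_2",
      "mets": {
        "m_2_1": -1,
        "m_2_2": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_2_2",
      "pathway": "P2",
      "exchange": false
    },
    {
      "id": "R_2_3",
      "mets": {
        "m_2_2": -1,
        "m_2_3": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_2_3",
      "pathway": "P2",
      "exchange": false
    },
    {
      "id": "R_2_4",
      "mets": {
        "m_2_3": -1,
        "m_2_4": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_2_4",
      "pathway": "P2",
      "exchange": false
    },
    {
      "id": "EX_out_P2",
      "mets": {
        "m_2_4": -1
      },
      "lb": -1000,
      "ub": 1000,
      "gpr": "",
      "pathway": "P2",
      "exchange": true
    },
    {
      "id": "EX_in_P3",
      "mets": {
        "m_3_0": -1
      },
      "lb": -1000,
      "ub": 1000,
      "gpr": "",
      "pathway": "P3",
      "exchange": true
    },
    {
      "id": "R_3_1",
      "mets": {
        "m_3_0": -1,
        "m_3_1": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_3_1",
      "pathway": "P3",
      "exchange": false
    },
    {
      "id": "R_3_2",
      "mets": {
        "m_3_1": -1,
        "m_3_2": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_3_2",
      "pathway": "P3",
      "exchange": false
    },
    {
      "id": "R_3_3",
      "mets": {
        "m_3_2": -1,
        "m_3_3": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_3_3",
      "pathway": "P3",
      "exchange": false
    },
    {
      "id": "R_3_4",
      "mets": {
        "m_3_3": -1,
        "m_3_4": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_3_4",
      "pathway": "P3",
      "exchange": false
    },
    {
      "id": "EX_out_P3",
      "mets": {
        "m_3_4": -1
      },
      "lb": -1000,
      "ub": 1000,
      "gpr": "",
      "pathway": "P3",
      "exchange": true
    },
    {
      "id": "EX_in_P4",
      "mets": {
        "m_4_0": -1
      },
      "lb": -1000,
      "ub": 1000,
      "gpr": "",
      "pathway": "P4",
      "exchange": true
    },
    {
      "id": "R_4_1",
      "mets": {
        "m_4_0": -1,
        "m_4_1": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "(g_R_4_1a and g_R_4_1b)",
      "pathway": "P4",
      "exchange": false
    },
    {
      "id": "R_4_2",
      "mets": {
        "m_4_1": -1,
        "m_4_2": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_4_2",
      "pathway": "P4",
      "exchange": false
    },
    {
      "id": "R_4_3",
      "mets": {
        "m_4_2": -1,
        "m_4_3": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_R_4_3",
      "pathway": "P4",
      "exchange": false
    },
    {
      "id": "R_4_4",
      "mets": {
        "m_4_3": -1,
        "m_4_4": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "(g_R_4_4a or g_R_4_4b)",
      "pathway": "P4",
      "exchange": false
    },
    {
      "id": "EX_out_P4",
      "mets": {
        "m_4_4": -1
      },
      "lb": -1000,
      "ub": 1000,
      "gpr": "",
      "pathway": "P4",
      "exchange": true
    },
    {
      "id": "CL_1_2",
      "mets": {
        "m_1_3": -1,
        "m_2_1": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_CL_1_2",
      "pathway": "P1",
      "exchange": false
    },
    {
      "id": "CL_2_3",
      "mets": {
        "m_2_3": -1,
        "m_3_1": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "g_CL_2_3",
      "pathway": "P2",
      "exchange": false
    },
    {
      "id": "CL_3_4",
      "mets": {
        "m_3_3": -1,
        "m_4_1": 1
      },
      "lb": 0,
      "ub": 1000,
      "gpr": "(g_CL_3_4a or g_CL_3_4b)",
      "pathway": "P3",
      "exchange": false
    }
  ]
}
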