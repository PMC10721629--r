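{
  "O": {
    "universe": [1, 10],
    "grid_points": 101,
    "input_mfs": {
      "1": [1, 1, 2],
      "2": [1, 2, 3],
      "3": [2, 3, 4],
      "4": [2, 4, 5],
      "5": [4, 5, 6],
      "6": [5, 6, 7],
      "7": [6, 7, 8],
      "8": [7, 8, 9],
      "9": [8, 9, 10],
      "10": [9, 10, 10]
    },
    "output_mfs": {
      "None": [1, 1, 2],
      "VL": [1, 2, 3],
      "L": [2, 3, 4, 5],
      "M": [4, 5, 6, 7],
      "H": [6, 7, 8, 9],
      "VH": [8, 9, 10, 10]
    },
    "rules": {
      "1": "None",
      "2": "VL",
      "3": "L",
      "4": "L",
      "5": "M",
      "6": "M",
      "7": "H",
      "8": "H",
      "9": "VH",
      "10": "VH"
    }
  },
  "S": {
    "universe": [1, 10],
    "grid_points": 101,
    "input_mfs": {
      "1": [1, 1, 2],
      "2": [1, 2, 3],
      "3": [2, 3, 4],
      "4": [2, 4, 5],
      "5": [4, 5, 6],
      "6": [5, 6, 7],
      "7": [6, 7, 8],
      "8": [7, 8, 9],
      "9": [8, 9, 10],
      "10": [9, 10, 10]
    },
    "output_mfs": {
      "VL": [1, 1, 2],
      "L": [1, 2, 3],
      "M": [2, 3, 5, 6],
      "H": [5, 6, 7, 8],
      "VH": [7, 8, 10, 10]
    },
    "rules": {
      "1": "VL",
      "2": "L",
      "3": "M",
      "4": "M",
      "5": "M",
      "6": "H",
      "7": "H",
      "8": "VH",
      "9": "VH",
      "10": "VH"
    }
  },
  "D": {
    "universe": [1, 10],
    "grid_points": 101,
    "input_mfs": {
      "1": [1, 1, 3],
      "3": [1, 3, 5],
      "5": [3, 5, 7],
      "7": [5, 7, 9],
      "9": [7, 9, 10],
      "10": [9, 10, 10]
    },
    "output_mfs": {
      "VL": [1, 1, 3],
      "L": [1, 3, 5],
      "M": [3, 5, 7],
      "H": [5, 7, 9],
      "VH": [7, 9, 10, 10]
    },
    "rules": {
      "1": "VL",
      "3": "L",
      "5": "M",
      "7": "H",
      "9": "VH",
      "10": "VH"
    }
  }
}
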