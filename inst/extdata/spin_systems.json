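{
  "format": "mrsproc-spin-systems-1",
  "comment": "Approximate 1H chemical shifts (ppm) and scalar couplings (Hz) compiled from the standard literature tables. Each metabolite is a list of independent spin groups; 'scale' multiplies the group signal (proton multiplicity of equivalent sites). Values are package defaults; users may supply their own files in the same layout.",
  "systems": {
    "NAA": [
      {"shifts_ppm": [2.008], "j_hz": [[0]], "scale": 3},
      {"shifts_ppm": [4.382, 2.6727, 2.4863],
       "j_hz": [[0, 3.861, 9.821], [3.861, 0, -15.592], [9.821, -15.592, 0]],
       "scale": 1}
    ],
    "Cr": [
      {"shifts_ppm": [3.027], "j_hz": [[0]], "scale": 3},
      {"shifts_ppm": [3.913], "j_hz": [[0]], "scale": 2}
    ],
    "Cho": [
      {"shifts_ppm": [3.185], "j_hz": [[0]], "scale": 9},
      {"shifts_ppm": [4.054, 3.501], "j_hz": [[0, 5.77], [5.77, 0]], "scale": 2}
    ],
    "Lac": [
      {"shifts_ppm": [4.0974, 1.3142, 1.3142, 1.3142],
       "j_hz": [[0, 6.933, 6.933, 6.933], [6.933, 0, 0, 0], [6.933, 0, 0, 0], [6.933, 0, 0, 0]],
       "scale": 1}
    ],
    "GABA": [
      {"shifts_ppm": [3.0128, 3.0128, 1.889, 1.889, 2.284, 2.284],
       "j_hz": [[0, -12.02, 5.372, 10.578, 0, 0],
                [-12.02, 0, 7.127, 6.982, 0, 0],
                [5.372, 7.127, 0, -13.87, 7.755, 7.432],
                [10.578, 6.982, -13.87, 0, 6.173, 7.933],
                [0, 0, 7.755, 6.173, 0, -10.744],
                [0, 0, 7.432, 7.933, -10.744, 0]],
       "scale": 1}
    ],
    "Glu": [
      {"shifts_ppm": [3.7433, 2.0375, 2.12, 2.3378, 2.352],
       "j_hz": [[0, 7.331, 4.651, 0, 0],
                [7.331, 0, -14.849, 6.413, 8.406],
                [4.651, -14.849, 0, 8.478, 6.875],
                [0, 6.413, 8.478, 0, -15.915],
                [0, 8.406, 6.875, -15.915, 0]],
       "scale": 1}
    ],
    "Gln": [
      {"shifts_ppm": [3.753, 2.129, 2.109, 2.432, 2.454],
       "j_hz": [[0, 5.847, 6.5, 0, 0],
                [5.847, 0, -14.504, 9.165, 6.347],
                [6.5, -14.504, 0, 6.324, 9.209],
                [0, 9.165, 6.324, 0, -15.371],
                [0, 6.347, 9.209, -15.371, 0]],
       "scale": 1}
    ],
    "mI": [
      {"shifts_ppm": [3.5217, 4.0538, 3.5217, 3.6144, 3.269, 3.6144],
       "j_hz": [[0, 2.889, 0, 0, 0, 9.998],
                [2.889, 0, 3.006, 0, 0, 0],
                [0, 3.006, 0, 9.997, 0, 0],
                [0, 0, 9.997, 0, 9.485, 0],
                [0, 0, 0, 9.485, 0, 9.482],
                [9.998, 0, 0, 0, 9.482, 0]],
       "scale": 1}
    ],
    "GSH": [
      {"shifts_ppm": [4.5608, 2.9264, 2.9747],
       "j_hz": [[0, 7.09, 4.71], [7.09, 0, -14.06], [4.71, -14.06, 0]],
       "scale": 1},
      {"shifts_ppm": [3.769], "j_hz": [[0]], "scale": 2}
    ],
    "Tau": [
      {"shifts_ppm": [3.4206, 3.4206, 3.2459, 3.2459],
       "j_hz": [[0, -12.438, 6.742, 6.464],
                [-12.438, 0, 6.403, 6.792],
                [6.742, 6.403, 0, -12.93],
                [6.464, 6.792, -12.93, 0]],
       "scale": 1}
    ]
  }
}
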