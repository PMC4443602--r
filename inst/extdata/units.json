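{
  "comment": "Atomic unit registry. Exponents over base dimensions (mass, length, time); scale converts one unit to the canonical internal base mg / m / day.",
  "units": {
    "1":    {"mass": 0, "length": 0, "time": 0, "scale": 1},
    "count":{"mass": 0, "length": 0, "time": 0, "scale": 1},
    "pct":  {"mass": 0, "length": 0, "time": 0, "scale": 0.01},

    "ng":   {"mass": 1, "length": 0, "time": 0, "scale": 1e-6},
    "ug":   {"mass": 1, "length": 0, "time": 0, "scale": 1e-3},
    "mg":   {"mass": 1, "length": 0, "time": 0, "scale": 1},
    "g":    {"mass": 1, "length": 0, "time": 0, "scale": 1e3},
    "kg":   {"mass": 1, "length": 0, "time": 0, "scale": 1e6},

    "nm":   {"mass": 0, "length": 1, "time": 0, "scale": 1e-9},
    "um":   {"mass": 0, "length": 1, "time": 0, "scale": 1e-6},
    "mm":   {"mass": 0, "length": 1, "time": 0, "scale": 1e-3},
    "cm":   {"mass": 0, "length": 1, "time": 0, "scale": 1e-2},
    "m":    {"mass": 0, "length": 1, "time": 0, "scale": 1},

    "l":    {"mass": 0, "length": 3, "time": 0, "scale": 1e-3},
    "ml":   {"mass": 0, "length": 3, "time": 0, "scale": 1e-6},
    "ul":   {"mass": 0, "length": 3, "time": 0, "scale": 1e-9},

    "s":    {"mass": 0, "length": 0, "time": 1, "scale": 1.1574074074074073e-05},
    "min":  {"mass": 0, "length": 0, "time": 1, "scale": 6.944444444444444e-04},
    "h":    {"mass": 0, "length": 0, "time": 1, "scale": 4.1666666666666664e-02},
    "day":  {"mass": 0, "length": 0, "time": 1, "scale": 1},
    "d":    {"mass": 0, "length": 0, "time": 1, "scale": 1},
    "week": {"mass": 0, "length": 0, "time": 1, "scale": 7},
    "year": {"mass": 0, "length": 0, "time": 1, "scale": 365.25}
  }
}
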