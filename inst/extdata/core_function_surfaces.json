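{
  "description": "Reference runtime surfaces shipped with blastpart: bivariate quadratic fits (seconds) for the five core BLASTN functions, profiled on the reference node type (Type V) with a single thread and a nucleotide short-read query set. Coefficients are in the order c1..c6 of c1*x^2 + c2*x*y + c3*y^2 + c4*x + c5*y + c6, with x = transform(database sequences / 1e6) and y = query sequences / 1e6. The log transform on the database axis is the natural logarithm.",
  "node_type": "V",
  "log_base": 2.718281828459045,
  "components": {
    "func_a": { "coefficients": [-3.0722, 143.6097, 3.7202, 22.4770, 881.6166, 30.0805], "x_transform": "log" },
    "func_b": { "coefficients": [0, 92.8758, 0, 0.1523, 244.7267, 0.4292], "x_transform": "identity" },
    "func_c": { "coefficients": [0, 4429.4587, 0, 57.7969, 94.9201, 0.1854], "x_transform": "identity" },
    "func_d": { "coefficients": [0, 19.2608, 0, -2.6282, 90.1090, 0.2345], "x_transform": "identity" },
    "func_e": { "coefficients": [-2.0973, 33.3526, 2.0294, 12.8749, 181.6523, 18.8566], "x_transform": "log" }
  }
}
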