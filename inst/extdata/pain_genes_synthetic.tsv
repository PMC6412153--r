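symbol
G00016
G00018
G00029
G00037
G00054
G00057
G00064
G00081
G00086
G00087
G00089
G00095
G00108
G00113
G00119
G00120
G00128
G00131
G00134
G00146
G00147
G00148
G00171
G00173
G00177
G00180
G00182
G00190
G00197
G00198
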