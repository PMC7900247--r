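schema_version: 1
condition: control
description: Identity bundle; the baseline parameter files apply unchanged.
intrinsic: {}
synaptic: {}
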