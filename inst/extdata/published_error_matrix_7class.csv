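class,active_cropland,short_fallow,herbaceous,open_woodland,closed_woodland,unvegetated,water
active_cropland,0.1578,0.0116,0.0266,0.0205,0,0.0055,0
short_fallow,0.002,0.0437,0.0035,0.0013,0,0,0
herbaceous,0.0019,0.0058,0.0691,0.0006,0.0006,0.001,0
open_woodland,0,0.0039,0.0097,0.3558,0,0.001,0
closed_woodland,0,0.0008,0.003,0.0129,0.2389,0,0
unvegetated,0.0002,0.0007,0.0004,0,0,0.0143,0.0003
water,0,0,0.0001,0,0,0,0.0066
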