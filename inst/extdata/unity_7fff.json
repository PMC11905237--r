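{"format_version":1,"length_unit":"mm","energy_label":"7X-FFF","dmax":13,"calibration":{"reference_field_side":100,"source_to_plane_distance":1385,"calibration_depth":50,"reference_dose":1,"reference_mu":100,"source_axis_distance":1435},"pdd":{"equivalent_square_sides":[20,30,40,50,70,100,200,220,254,272,302,310],"depths":[5,10,13,20,30,50,80,100,130],"values":[[0.88,0.96999999999999997,1,0.96799999999999997,0.92200000000000004,0.82999999999999996,0.71999999999999997,0.63400000000000001,0.52800000000000002],[0.89000000000000001,0.97499999999999998,1,0.97499999999999998,0.93500000000000005,0.83899999999999997,0.72999999999999998,0.64900000000000002,0.53800000000000003],[0.89500000000000002,0.97799999999999998,1,0.97999999999999998,0.94499999999999995,0.84799999999999998,0.73999999999999999,0.66200000000000003,0.55100000000000005],[0.90000000000000002,0.97999999999999998,1,0.98499999999999999,0.95199999999999996,0.85699999999999998,0.75,0.67400000000000004,0.56299999999999994],[0.90500000000000003,0.98199999999999998,1,0.98999999999999999,0.95999999999999996,0.86799999999999999,0.76500000000000001,0.69099999999999995,0.58299999999999996],[0.91000000000000003,0.98499999999999999,1,0.99299999999999999,0.96999999999999997,0.88,0.78000000000000003,0.70799999999999996,0.60199999999999998],[0.91800000000000004,0.98899999999999999,1,0.99380000000000002,0.97150000000000003,0.88400000000000001,0.78800000000000003,0.72199999999999998,0.626],[0.92000000000000004,0.98999999999999999,1,0.99399999999999999,0.97199999999999998,0.88500000000000001,0.79000000000000004,0.72399999999999998,0.629],[0.92100000000000004,0.99050000000000005,1,0.99419999999999997,0.97250000000000003,0.88600000000000001,0.79200000000000004,0.72599999999999998,0.63200000000000001],[0.92200000000000004,0.99080000000000001,1,0.99439999999999995,0.97299999999999998,0.88700000000000001,0.79300000000000004,0.72799999999999998,0.63400000000000001],[0.92500000000000004,0.99099999999999999,1,0.995,0.97399999999999998,0.88800000000000001,0.79500000000000004,0.72999999999999998,0.63600000000000001],[0.92549999999999999,0.99119999999999997,1,0.99519999999999997,0.97419999999999995,0.88849999999999996,0.79549999999999998,0.73050000000000004,0.63649999999999995]],"nominal_ssd":1335},"output_factors":{"equivalent_square_sides":[20,30,50,100,150,220,290,340],"scp_values":[0.93500000000000005,0.95499999999999996,0.97699999999999998,1,1.022,1.0549999999999999,1.085,1.105],"reference_depth":100,"reference_ssd":1335},"cryostat":{"gantry_angles":[0,2,4,6,8,18,20,22,24,26,28,30,32,34,36,38,40,42,44,46,48,50,52,54,56,58,60,62,64,66,68,70,72,74,76,78,80,82,84,86,88,90,92,94,96,98,100,102,104,106,108,110,112,114,116,118,120,122,124,126,128,130,132,134,136,138,140,142,144,146,148,150,152,154,156,158,160,162,164,166,168,170,172,174,176,178,180,182,184,186,188,190,192,194,196,198,200,202,204,206,208,210,212,214,216,218,220,222,224,226,228,230,232,234,236,238,240,242,244,246,248,250,252,254,256,258,260,262,264,266,268,270,272,274,276,278,280,282,284,286,288,290,292,294,296,298,300,302,304,306,308,310,312,314,316,318,320,322,324,326,328,330,332,334,336,338,340,342,344,346,348,350,352,354,356,358],"correction_factors":[1,1,1.0000100000000001,1.00003,1.0000599999999999,1.0002800000000001,1.00034,1.00041,1.00048,1.0005500000000001,1.0006200000000001,1.0006999999999999,1.00078,1.0008600000000001,1.0009399999999999,1.00101,1.00109,1.00116,1.0012300000000001,1.0013000000000001,1.00136,1.0014099999999999,1.00146,1.0015000000000001,1.00153,1.0015499999999999,1.00156,1.00156,1.00156,1.0015400000000001,1.0015000000000001,1.00146,1.0014000000000001,1.0013300000000001,1.0012399999999999,1.0011399999999999,1.0010300000000001,1.0008999999999999,1.0007600000000001,1.00061,1.0004299999999999,1.0002500000000001,1.0000500000000001,0.99983999999999995,0.99961,0.99936999999999998,0.99912000000000001,0.99885999999999997,0.99858000000000002,0.99829999999999997,0.998,0.99770000000000003,0.99738000000000004,0.99705999999999995,0.99673,0.99639999999999995,0.99605999999999995,0.99572000000000005,0.99538000000000004,0.99502999999999997,0.99468000000000001,0.99434,0.99399999999999999,0.99365000000000003,0.99331999999999998,0.99299000000000004,0.99265999999999999,0.99234999999999995,0.99204000000000003,0.99173999999999995,0.99145000000000005,0.99117,0.99090999999999996,0.99065999999999999,0.99043000000000003,0.99021000000000003,0.98999999999999999,0.98982000000000003,0.98965000000000003,0.98950000000000005,0.98936999999999997,0.98926000000000003,0.98916000000000004,0.98909000000000002,0.98904000000000003,0.98900999999999994,0.98899999999999999,0.98900999999999994,0.98904000000000003,0.98909000000000002,0.98916000000000004,0.98926000000000003,0.98936999999999997,0.98950000000000005,0.98965000000000003,0.98982000000000003,0.98999999999999999,0.99021000000000003,0.99043000000000003,0.99065999999999999,0.99090999999999996,0.99117,0.99145000000000005,0.99173999999999995,0.99204000000000003,0.99234999999999995,0.99265999999999999,0.99299000000000004,0.99331999999999998,0.99365000000000003,0.99399999999999999,0.99434,0.99468000000000001,0.99502999999999997,0.99538000000000004,0.99572000000000005,0.99605999999999995,0.99639999999999995,0.99673,0.99705999999999995,0.99738000000000004,0.99770000000000003,0.998,0.99829999999999997,0.99858000000000002,0.99885999999999997,0.99912000000000001,0.99936999999999998,0.99961,0.99983999999999995,1.0000500000000001,1.0002500000000001,1.0004299999999999,1.00061,1.0007600000000001,1.0008999999999999,1.0010300000000001,1.0011399999999999,1.0012399999999999,1.0013300000000001,1.0014000000000001,1.00146,1.0015000000000001,1.0015400000000001,1.00156,1.00156,1.00156,1.0015499999999999,1.00153,1.0015000000000001,1.00146,1.0014099999999999,1.00136,1.0013000000000001,1.0012300000000001,1.00116,1.00109,1.00101,1.0009399999999999,1.0008600000000001,1.00078,1.0006999999999999,1.0006200000000001,1.0005500000000001,1.00048,1.00041,1.00034,1.0002800000000001,1.0002200000000001,1.00017,1.00013,1.0000899999999999,1.0000599999999999,1.00003,1.0000100000000001,1]},"mlc":{"transmission":0.0054999999999999997,"dosimetric_leaf_gap":0.01,"leaf_count":160,"leaf_width":7.1749999999999998},"profiles":{"sides":[20,100,220,340],"penumbra_width":[5,6.5,7.5,8],"asymmetry_shift":[2,2,2,2],"horn_slope":[0.002,0.002,0.002,0.002],"depth_broadening":[0.02,0.02,0.02,0.02]}}
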