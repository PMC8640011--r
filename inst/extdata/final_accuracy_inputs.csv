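dataset,architecture,detection_rate,iou_90,final_accuracy
CBIS-DDSM,connected_unets,95.7,90.05,86.18
CBIS-DDSM,connected_aunets,95.7,90.24,86.36
CBIS-DDSM,connected_resunets,95.7,90.82,86.91
INbreast,connected_unets,98.1,94.06,92.27
INbreast,connected_aunets,98.1,94.63,92.83
INbreast,connected_resunets,98.1,94.83,93.03
Private,connected_unets,98,96.99,95.05
Private,connected_aunets,98,97.22,95.27
Private,connected_resunets,98,97.34,95.39
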