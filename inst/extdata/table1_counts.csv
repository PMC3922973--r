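method,total_signals,probable_matches,possible_matches,band5_matches,false_positives
isodata,158,44,16,1,97
kmeans,102,42,11,0,49
threshold_pan,64,43,14,0,7
threshold_band5,101,49,15,13,24
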