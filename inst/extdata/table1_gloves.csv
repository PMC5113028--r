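glove,mechanism,av_certification,grip_strength_reduction_pct
gel,Viscoelastic Gel,Not classified as AV glove,40
air_bladder,Air Bladder,Classified as AV glove,30
air_bubble,Air Bubble,Marginally classified as AV glove,34
neoprene,Neoprene-dipped,Not classified as AV glove,26
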