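tool,mode,location,glove,ty,txz,txzy
stone_hammer_chisel,unweighted,fingertip,gel,1.25,0.98,1.19
stone_hammer_chisel,weighted,fingertip,gel,1.17,1.03,1.14
stone_hammer_chisel,unweighted,fingertip,air_bladder,1.46,1.04,1.38
stone_hammer_chisel,weighted,fingertip,air_bladder,1.18,1.06,1.16
stone_hammer_chisel,unweighted,fingertip,air_bubble,1.24,0.89,1.17
stone_hammer_chisel,weighted,fingertip,air_bubble,1.12,1.00,1.10
stone_hammer_chisel,unweighted,fingertip,neoprene,0.95,0.64,0.89
stone_hammer_chisel,weighted,fingertip,neoprene,1.10,1.02,1.09
stone_hammer_chisel,unweighted,proximal,gel,1.23,1.13,1.21
stone_hammer_chisel,weighted,proximal,gel,1.13,0.98,1.10
stone_hammer_chisel,unweighted,proximal,air_bladder,1.01,0.97,1.00
stone_hammer_chisel,weighted,proximal,air_bladder,1.08,0.92,1.05
stone_hammer_chisel,unweighted,proximal,air_bubble,0.97,1.12,1.01
stone_hammer_chisel,weighted,proximal,air_bubble,1.01,1.01,1.01
stone_hammer_chisel,unweighted,proximal,neoprene,0.95,1.03,0.97
stone_hammer_chisel,weighted,proximal,neoprene,1.06,1.01,1.05
stone_hammer_handle,unweighted,fingertip,gel,1.03,1.02,1.02
stone_hammer_handle,weighted,fingertip,gel,1.11,1.05,1.06
stone_hammer_handle,unweighted,fingertip,air_bladder,1.13,1.07,1.07
stone_hammer_handle,weighted,fingertip,air_bladder,1.04,1.06,1.06
stone_hammer_handle,unweighted,fingertip,air_bubble,1.09,0.97,0.99
stone_hammer_handle,weighted,fingertip,air_bubble,1.07,1.05,1.06
stone_hammer_handle,unweighted,fingertip,neoprene,1.06,0.83,0.85
stone_hammer_handle,weighted,fingertip,neoprene,1.18,1.10,1.12
stone_hammer_handle,unweighted,proximal,gel,1.19,1.02,1.04
stone_hammer_handle,weighted,proximal,gel,1.06,0.86,0.91
stone_hammer_handle,unweighted,proximal,air_bladder,1.07,0.91,0.93
stone_hammer_handle,weighted,proximal,air_bladder,1.11,0.86,0.92
stone_hammer_handle,unweighted,proximal,air_bubble,1.02,1.13,1.12
stone_hammer_handle,weighted,proximal,air_bubble,1.06,0.94,0.97
stone_hammer_handle,unweighted,proximal,neoprene,1.07,1.09,1.09
stone_hammer_handle,weighted,proximal,neoprene,1.14,0.98,1.01
golf_club_head,unweighted,fingertip,gel,1.17,0.99,1.05
golf_club_head,weighted,fingertip,gel,1.11,1.06,1.07
golf_club_head,unweighted,fingertip,air_bladder,1.63,1.04,1.27
golf_club_head,weighted,fingertip,air_bladder,1.21,1.06,1.09
golf_club_head,unweighted,fingertip,air_bubble,1.28,0.95,1.07
golf_club_head,weighted,fingertip,air_bubble,1.12,1.11,1.12
golf_club_head,unweighted,fingertip,neoprene,0.94,0.80,0.86
golf_club_head,weighted,fingertip,neoprene,1.08,1.18,1.16
golf_club_head,unweighted,proximal,gel,1.14,1.05,1.07
golf_club_head,weighted,proximal,gel,1.01,0.78,0.82
golf_club_head,unweighted,proximal,air_bladder,0.89,0.92,0.91
golf_club_head,weighted,proximal,air_bladder,1.03,0.80,0.84
golf_club_head,unweighted,proximal,air_bubble,1.02,1.01,1.01
golf_club_head,weighted,proximal,air_bubble,1.01,0.75,0.79
golf_club_head,unweighted,proximal,neoprene,0.95,0.94,0.94
golf_club_head,weighted,proximal,neoprene,1.03,0.83,0.86
needle_scaler,unweighted,fingertip,gel,1.16,1.01,1.13
needle_scaler,weighted,fingertip,gel,1.20,1.04,1.19
needle_scaler,unweighted,fingertip,air_bladder,1.27,1.06,1.22
needle_scaler,weighted,fingertip,air_bladder,1.07,1.06,1.07
needle_scaler,unweighted,fingertip,air_bubble,1.12,0.93,1.07
needle_scaler,weighted,fingertip,air_bubble,1.06,1.00,1.06
needle_scaler,unweighted,fingertip,neoprene,1.13,0.74,1.05
needle_scaler,weighted,fingertip,neoprene,1.27,1.04,1.25
needle_scaler,unweighted,proximal,gel,1.18,1.09,1.16
needle_scaler,weighted,proximal,gel,1.14,0.98,1.13
needle_scaler,unweighted,proximal,air_bladder,1.08,0.94,1.05
needle_scaler,weighted,proximal,air_bladder,1.16,0.94,1.14
needle_scaler,unweighted,proximal,air_bubble,1.04,1.13,1.06
needle_scaler,weighted,proximal,air_bubble,1.07,1.03,1.06
needle_scaler,unweighted,proximal,neoprene,1.04,1.07,1.05
needle_scaler,weighted,proximal,neoprene,1.10,1.03,1.10
steel_bucking_bar_b,unweighted,fingertip,gel,1.14,1.02,1.12
steel_bucking_bar_b,weighted,fingertip,gel,1.08,1.04,1.06
steel_bucking_bar_b,unweighted,fingertip,air_bladder,1.47,1.05,1.41
steel_bucking_bar_b,weighted,fingertip,air_bladder,1.05,1.03,1.04
steel_bucking_bar_b,unweighted,fingertip,air_bubble,1.21,0.98,1.18
steel_bucking_bar_b,weighted,fingertip,air_bubble,1.05,1.05,1.05
steel_bucking_bar_b,unweighted,fingertip,neoprene,0.98,0.96,0.98
steel_bucking_bar_b,weighted,fingertip,neoprene,1.12,1.12,1.12
steel_bucking_bar_b,unweighted,proximal,gel,1.16,1.03,1.14
steel_bucking_bar_b,weighted,proximal,gel,1.00,0.90,0.97
steel_bucking_bar_b,unweighted,proximal,air_bladder,0.96,0.94,0.96
steel_bucking_bar_b,weighted,proximal,air_bladder,1.06,0.92,1.02
steel_bucking_bar_b,unweighted,proximal,air_bubble,1.01,1.05,1.01
steel_bucking_bar_b,weighted,proximal,air_bubble,0.98,0.87,0.94
steel_bucking_bar_b,unweighted,proximal,neoprene,0.98,1.03,0.99
steel_bucking_bar_b,weighted,proximal,neoprene,1.05,0.92,1.01
tungsten_bucking_bar_e,unweighted,fingertip,gel,1.14,1.02,1.11
tungsten_bucking_bar_e,weighted,fingertip,gel,1.06,1.04,1.05
tungsten_bucking_bar_e,unweighted,fingertip,air_bladder,1.41,1.05,1.34
tungsten_bucking_bar_e,weighted,fingertip,air_bladder,1.03,1.03,1.03
tungsten_bucking_bar_e,unweighted,fingertip,air_bubble,1.19,1.00,1.16
tungsten_bucking_bar_e,weighted,fingertip,air_bubble,1.03,1.05,1.04
tungsten_bucking_bar_e,unweighted,fingertip,neoprene,1.01,1.02,1.01
tungsten_bucking_bar_e,weighted,fingertip,neoprene,1.09,1.13,1.11
tungsten_bucking_bar_e,unweighted,proximal,gel,1.16,0.99,1.13
tungsten_bucking_bar_e,weighted,proximal,gel,1.00,0.89,0.96
tungsten_bucking_bar_e,unweighted,proximal,air_bladder,0.99,0.93,0.98
tungsten_bucking_bar_e,weighted,proximal,air_bladder,1.04,0.91,1.00
tungsten_bucking_bar_e,unweighted,proximal,air_bubble,1.00,1.00,1.00
tungsten_bucking_bar_e,weighted,proximal,air_bubble,0.98,0.86,0.94
tungsten_bucking_bar_e,unweighted,proximal,neoprene,0.99,1.00,1.00
tungsten_bucking_bar_e,weighted,proximal,neoprene,1.04,0.91,0.99
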