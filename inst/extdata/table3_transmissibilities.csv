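tool,mode,location,glove,ty,txz,txzy
vibrating_fork,unweighted,fingertip,gel,1.05,1.02,1.03
vibrating_fork,weighted,fingertip,gel,1.01,1.03,1.03
vibrating_fork,unweighted,fingertip,air_bladder,1.05,1.03,1.04
vibrating_fork,weighted,fingertip,air_bladder,1.00,1.02,1.01
vibrating_fork,unweighted,fingertip,air_bubble,1.03,1.02,1.02
vibrating_fork,weighted,fingertip,air_bubble,0.99,1.04,1.03
vibrating_fork,unweighted,fingertip,neoprene,1.06,1.04,1.05
vibrating_fork,weighted,fingertip,neoprene,1.03,1.11,1.09
vibrating_fork,unweighted,proximal,gel,1.03,0.94,0.96
vibrating_fork,weighted,proximal,gel,0.98,0.90,0.92
vibrating_fork,unweighted,proximal,air_bladder,1.05,0.91,0.94
vibrating_fork,weighted,proximal,air_bladder,1.02,0.92,0.94
vibrating_fork,unweighted,proximal,air_bubble,0.99,0.92,0.93
vibrating_fork,weighted,proximal,air_bubble,0.97,0.85,0.88
vibrating_fork,unweighted,proximal,neoprene,1.05,0.93,0.95
vibrating_fork,weighted,proximal,neoprene,1.03,0.90,0.93
pavement_tamper,unweighted,fingertip,gel,1.06,1.02,1.03
pavement_tamper,weighted,fingertip,gel,1.01,1.01,1.01
pavement_tamper,unweighted,fingertip,air_bladder,1.10,1.04,1.05
pavement_tamper,weighted,fingertip,air_bladder,1.00,1.01,1.01
pavement_tamper,unweighted,fingertip,air_bubble,1.06,1.01,1.02
pavement_tamper,weighted,fingertip,air_bubble,1.00,1.02,1.01
pavement_tamper,unweighted,fingertip,neoprene,1.07,1.06,1.06
pavement_tamper,weighted,fingertip,neoprene,1.03,1.07,1.04
pavement_tamper,unweighted,proximal,gel,1.02,1.00,1.00
pavement_tamper,weighted,proximal,gel,0.98,0.97,0.97
pavement_tamper,unweighted,proximal,air_bladder,1.01,0.97,0.97
pavement_tamper,weighted,proximal,air_bladder,1.00,0.99,0.99
pavement_tamper,unweighted,proximal,air_bubble,0.98,1.00,0.99
pavement_tamper,weighted,proximal,air_bubble,0.99,0.96,0.96
pavement_tamper,unweighted,proximal,neoprene,1.02,1.01,1.01
pavement_tamper,weighted,proximal,neoprene,1.01,0.98,0.99
chipping_hammer,unweighted,fingertip,gel,1.08,0.94,0.96
chipping_hammer,weighted,fingertip,gel,1.07,1.07,1.07
chipping_hammer,unweighted,fingertip,air_bladder,1.71,1.00,1.13
chipping_hammer,weighted,fingertip,air_bladder,1.11,1.05,1.05
chipping_hammer,unweighted,fingertip,air_bubble,1.25,0.89,0.95
chipping_hammer,weighted,fingertip,air_bubble,1.06,1.12,1.11
chipping_hammer,unweighted,fingertip,neoprene,0.86,0.71,0.74
chipping_hammer,weighted,fingertip,neoprene,1.07,1.19,1.18
chipping_hammer,unweighted,proximal,gel,1.12,1.15,1.15
chipping_hammer,weighted,proximal,gel,0.98,0.86,0.87
chipping_hammer,unweighted,proximal,air_bladder,0.82,0.98,0.96
chipping_hammer,weighted,proximal,air_bladder,1.03,0.87,0.88
chipping_hammer,unweighted,proximal,air_bubble,1.03,1.06,1.06
chipping_hammer,weighted,proximal,air_bubble,0.96,0.80,0.81
chipping_hammer,unweighted,proximal,neoprene,0.92,0.95,0.95
chipping_hammer,weighted,proximal,neoprene,1.02,0.86,0.87
rivet_hammer,unweighted,fingertip,gel,1.13,0.98,1.02
rivet_hammer,weighted,fingertip,gel,1.08,1.04,1.05
rivet_hammer,unweighted,fingertip,air_bladder,1.62,1.03,1.24
rivet_hammer,weighted,fingertip,air_bladder,1.15,1.03,1.05
rivet_hammer,unweighted,fingertip,air_bubble,1.25,0.90,1.01
rivet_hammer,weighted,fingertip,air_bubble,1.09,1.04,1.05
rivet_hammer,unweighted,fingertip,neoprene,0.91,0.73,0.79
rivet_hammer,weighted,fingertip,neoprene,1.09,1.12,1.12
rivet_hammer,unweighted,proximal,gel,1.16,1.12,1.13
rivet_hammer,weighted,proximal,gel,1.08,0.91,0.94
rivet_hammer,unweighted,proximal,air_bladder,0.89,0.97,0.95
rivet_hammer,weighted,proximal,air_bladder,1.03,0.92,0.94
rivet_hammer,unweighted,proximal,air_bubble,1.02,1.10,1.08
rivet_hammer,weighted,proximal,air_bubble,1.00,0.89,0.91
rivet_hammer,unweighted,proximal,neoprene,0.94,1.01,0.99
rivet_hammer,weighted,proximal,neoprene,1.05,0.93,0.94
impact_wrench,unweighted,fingertip,gel,1.15,0.96,0.99
impact_wrench,weighted,fingertip,gel,1.08,1.02,1.04
impact_wrench,unweighted,fingertip,air_bladder,1.63,1.03,1.14
impact_wrench,weighted,fingertip,air_bladder,1.14,1.05,1.07
impact_wrench,unweighted,fingertip,air_bubble,1.26,0.86,0.93
impact_wrench,weighted,fingertip,air_bubble,1.09,0.99,1.01
impact_wrench,unweighted,fingertip,neoprene,0.92,0.59,0.65
impact_wrench,weighted,fingertip,neoprene,1.09,0.98,1.01
impact_wrench,unweighted,proximal,gel,1.16,1.15,1.16
impact_wrench,weighted,proximal,gel,1.06,1.00,1.01
impact_wrench,unweighted,proximal,air_bladder,0.90,0.98,0.97
impact_wrench,weighted,proximal,air_bladder,1.04,0.94,0.96
impact_wrench,unweighted,proximal,air_bubble,1.02,1.12,1.11
impact_wrench,weighted,proximal,air_bubble,0.99,1.01,1.01
impact_wrench,unweighted,proximal,neoprene,0.95,1.01,1.00
impact_wrench,weighted,proximal,neoprene,1.04,1.00,1.01
vertical_grinder,unweighted,fingertip,gel,1.16,0.96,1.08
vertical_grinder,weighted,fingertip,gel,1.20,1.03,1.08
vertical_grinder,unweighted,fingertip,air_bladder,1.75,1.03,1.48
vertical_grinder,weighted,fingertip,air_bladder,1.61,1.05,1.25
vertical_grinder,unweighted,fingertip,air_bubble,1.29,0.87,1.13
vertical_grinder,weighted,fingertip,air_bubble,1.25,0.98,1.07
vertical_grinder,unweighted,fingertip,neoprene,0.86,0.66,0.78
vertical_grinder,weighted,fingertip,neoprene,0.91,1.14,1.08
vertical_grinder,unweighted,proximal,gel,1.15,1.13,1.14
vertical_grinder,weighted,proximal,gel,1.19,0.98,1.05
vertical_grinder,unweighted,proximal,air_bladder,0.84,0.99,0.91
vertical_grinder,weighted,proximal,air_bladder,0.92,1.02,0.99
vertical_grinder,unweighted,proximal,air_bubble,1.03,1.11,1.06
vertical_grinder,weighted,proximal,air_bubble,1.00,1.01,1.01
vertical_grinder,unweighted,proximal,neoprene,0.91,0.98,0.94
vertical_grinder,weighted,proximal,neoprene,0.92,0.97,0.95
pavement_cutting_saw,unweighted,fingertip,gel,0.98,0.99,0.99
pavement_cutting_saw,weighted,fingertip,gel,0.99,0.99,0.99
pavement_cutting_saw,unweighted,fingertip,air_bladder,1.08,1.06,1.07
pavement_cutting_saw,weighted,fingertip,air_bladder,0.97,1.06,1.04
pavement_cutting_saw,unweighted,fingertip,air_bubble,1.18,0.98,1.02
pavement_cutting_saw,weighted,fingertip,air_bubble,1.16,1.00,1.03
pavement_cutting_saw,unweighted,fingertip,neoprene,1.12,1.11,1.11
pavement_cutting_saw,weighted,fingertip,neoprene,1.20,1.20,1.20
pavement_cutting_saw,unweighted,proximal,gel,1.17,1.12,1.13
pavement_cutting_saw,weighted,proximal,gel,1.11,1.10,1.10
pavement_cutting_saw,unweighted,proximal,air_bladder,1.04,1.00,1.01
pavement_cutting_saw,weighted,proximal,air_bladder,1.05,1.02,1.02
pavement_cutting_saw,unweighted,proximal,air_bubble,1.00,1.12,1.10
pavement_cutting_saw,weighted,proximal,air_bubble,1.01,1.09,1.07
pavement_cutting_saw,unweighted,proximal,neoprene,1.10,1.15,1.14
pavement_cutting_saw,weighted,proximal,neoprene,1.14,1.13,1.13
sander,unweighted,fingertip,gel,1.13,0.98,0.98
sander,weighted,fingertip,gel,1.02,0.98,0.98
sander,unweighted,fingertip,air_bladder,1.66,1.05,1.06
sander,weighted,fingertip,air_bladder,1.15,1.05,1.06
sander,unweighted,fingertip,air_bubble,1.30,0.95,0.95
sander,weighted,fingertip,air_bubble,1.22,0.98,0.98
sander,unweighted,fingertip,neoprene,0.95,1.06,1.06
sander,weighted,fingertip,neoprene,1.14,1.23,1.23
sander,unweighted,proximal,gel,1.12,1.15,1.15
sander,weighted,proximal,gel,1.07,1.15,1.15
sander,unweighted,proximal,air_bladder,0.86,1.03,1.03
sander,weighted,proximal,air_bladder,0.98,1.07,1.07
sander,unweighted,proximal,air_bubble,1.03,1.12,1.12
sander,weighted,proximal,air_bubble,1.00,1.11,1.11
sander,unweighted,proximal,neoprene,0.96,1.11,1.11
sander,weighted,proximal,neoprene,1.09,1.15,1.15
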