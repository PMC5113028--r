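source_table,tool,mode,ay_ms2,axz_ms2,at_ms2,identity_ok
Table 3,vibrating_fork,unweighted,10.35,23.02,25.24,TRUE
Table 3,vibrating_fork,weighted,5.68,10.74,12.15,TRUE
Table 3,pavement_tamper,unweighted,14.25,29.68,33.2,FALSE
Table 3,pavement_tamper,weighted,10.17,12.67,18.19,FALSE
Table 3,chipping_hammer,unweighted,27.68,67.86,73.3,TRUE
Table 3,chipping_hammer,weighted,2.7,11.84,12.16,FALSE
Table 3,rivet_hammer,unweighted,92.25,143.34,170.46,TRUE
Table 3,rivet_hammer,weighted,7.71,18.92,20.44,TRUE
Table 3,impact_wrench,unweighted,36.53,86.26,93.68,TRUE
Table 3,impact_wrench,weighted,3.23,5.73,6.58,TRUE
Table 3,vertical_grinder,unweighted,154.84,136.14,206.18,TRUE
Table 3,vertical_grinder,weighted,6.3,9.41,11.33,TRUE
Table 3,pavement_cutting_saw,unweighted,46.1,94.97,105.58,TRUE
Table 3,pavement_cutting_saw,weighted,5.3,10.9,12.12,TRUE
Table 3,sander,unweighted,11.59,94.63,95.34,TRUE
Table 3,sander,weighted,0.81,9.87,9.9,TRUE
Table 5,stone_hammer_chisel,unweighted,217.55,120.82,248.84,TRUE
Table 5,stone_hammer_chisel,weighted,17.35,8.46,19.31,TRUE
Table 5,stone_hammer_handle,unweighted,60.01,173.69,183.77,TRUE
Table 5,stone_hammer_handle,weighted,9.9,18.88,21.31,TRUE
Table 5,golf_club_head,unweighted,14.77,19.89,24.79,FALSE
Table 5,golf_club_head,weighted,1.04,2.37,2.59,TRUE
Table 5,needle_scaler,unweighted,73.16,41.22,83.97,TRUE
Table 5,needle_scaler,weighted,11.38,3.45,11.89,TRUE
Table 5,steel_bucking_bar_b,unweighted,79.94,35.33,87.4,TRUE
Table 5,steel_bucking_bar_b,weighted,12.07,8.67,14.86,TRUE
Table 5,tungsten_bucking_bar_e,unweighted,27.09,13.42,30.23,TRUE
Table 5,tungsten_bucking_bar_e,weighted,5.17,3.96,6.51,TRUE
Table 4,Fast Fork - Tines,weighted,NA,NA,26.56,NA
Table 4,Fast Fork - Wire Mesh,weighted,NA,NA,12.15,NA
Table 4,Slow Fork - Tines,weighted,NA,NA,7.99,NA
Table 4,Slow Fork - Wire Mesh,weighted,NA,NA,3.92,NA
Table 4,Hand-held Tractor - Rota filling,weighted,NA,NA,6.8,NA
Table 4,Hand-held Tractor - Rota pudding,weighted,NA,NA,5.27,NA
Table 4,Hand-held Tractor - Transportation,weighted,NA,NA,8.15,NA
Table 4,Bench Rammer,weighted,NA,NA,30.5,NA
Table 4,Floor Rammer,weighted,NA,NA,23.69,NA
Table 4,Pavement Tamper,weighted,NA,NA,18.19,NA
Table 4,Impact Wrench A,weighted,NA,NA,6.58,NA
Table 4,Impact Wrench B,weighted,NA,NA,2.69,NA
Table 4,Impact Wrench C,weighted,NA,NA,9.01,NA
Table 4,Impact Wrench D,weighted,NA,NA,8.09,NA
Table 4,Rivet A,weighted,NA,NA,20.44,NA
Table 4,Rivet B,weighted,NA,NA,15.8,NA
Table 4,Rivet C,weighted,NA,NA,27.54,NA
Table 4,Rivet D,weighted,NA,NA,29.11,NA
Table 4,Rivet E,weighted,NA,NA,13.48,NA
Table 4,Rivet F,weighted,NA,NA,17.58,NA
Table 4,Rivet G,weighted,NA,NA,20.55,NA
Table 4,Rivet H,weighted,NA,NA,20.65,NA
Table 4,Rivet S1,weighted,NA,NA,2.81,NA
Table 4,Rivet S2,weighted,NA,NA,2.37,NA
Table 4,Rivet S3,weighted,NA,NA,2.52,NA
Table 4,Rivet S4,weighted,NA,NA,5.22,NA
Table 4,Steel Bucking Bar B,weighted,NA,NA,14.86,NA
Table 4,Tungsten Bucking Bar E,weighted,NA,NA,6.51,NA
Table 4,CH Bucking Bar,weighted,NA,NA,15.39,NA
Table 4,DF Bucking Bar,weighted,NA,NA,27.74,NA
Table 4,Foot Bucking Bar,weighted,NA,NA,12.5,NA
Table 4,L Bucking Bar,weighted,NA,NA,7.65,NA
Table 4,TR Bucking Bar 1,weighted,NA,NA,14.34,NA
Table 4,TR Bucking Bar 2,weighted,NA,NA,21.24,NA
Table 4,Paving Breaker,weighted,NA,NA,52.26,NA
Table 4,Clay Spade,weighted,NA,NA,27.25,NA
Table 4,Chipping Hammer B,weighted,NA,NA,12.16,NA
Table 4,Chipping Hammer A,weighted,NA,NA,10.95,NA
Table 4,Impact Drill,weighted,NA,NA,9.08,NA
Table 4,Rotary Hammer,weighted,NA,NA,18.91,NA
Table 4,Rock Drill,weighted,NA,NA,11.7,NA
Table 4,Stone Hammer - Chisel,weighted,NA,NA,19.31,NA
Table 4,Stone Hammer - Handle,weighted,NA,NA,21.31,NA
Table 4,3kg Impact Drill,weighted,NA,NA,11.71,NA
Table 4,6kg Impact Drill,weighted,NA,NA,9.44,NA
Table 4,Needle Scaler,weighted,NA,NA,11.89,NA
Table 4,Scabbler,weighted,NA,NA,12.8,NA
Table 4,PC Sander,weighted,NA,NA,9.9,NA
Table 4,P Air Sander,weighted,NA,NA,2.69,NA
Table 4,Belt Sander,weighted,NA,NA,3.8,NA
Table 4,BD Sander,weighted,NA,NA,17.8,NA
Table 4,Orbit Sander,weighted,NA,NA,4.79,NA
Table 4,Pavement Cutting Saw,weighted,NA,NA,12.12,NA
Table 4,Miter Saw,weighted,NA,NA,5.47,NA
Table 4,Jig Saw,weighted,NA,NA,6.77,NA
Table 4,Circular Saw,weighted,NA,NA,6.11,NA
Table 4,Reciprocating Saw,weighted,NA,NA,5.78,NA
Table 4,Chain Saw,weighted,NA,NA,9.93,NA
Table 4,Multi-use Tool,weighted,NA,NA,11.84,NA
Table 4,Golf Club Head - Grinding,weighted,NA,NA,2.59,NA
Table 4,Vertical Grinder ship yard,weighted,NA,NA,11.33,NA
Table 4,7 In Grinder,weighted,NA,NA,6.1,NA
Table 4,4.5 In Grinder,weighted,NA,NA,11.99,NA
Table 4,Electric Angular Grinder,weighted,NA,NA,9.99,NA
Table 4,Angular Grinder,weighted,NA,NA,5.47,NA
Table 4,Die Grinder,weighted,NA,NA,1.69,NA
Table 4,Pencil Grinder,weighted,NA,NA,1.57,NA
Table 4,Hedge Trimmer,weighted,NA,NA,13.48,NA
Table 4,Strimmer,weighted,NA,NA,7.11,NA
Table 4,Trimmer,weighted,NA,NA,13.48,NA
Table 4,Angular Nutrunner,weighted,NA,NA,2.88,NA
Table 4,Straight Nutrunner 1,weighted,NA,NA,2.42,NA
Table 4,Straight Nutrunner 2,weighted,NA,NA,2.17,NA
Table 4,Straight Nutrunner 3,weighted,NA,NA,2.93,NA
Table 4,Angular Nutrunner,weighted,NA,NA,16.7,NA
Table 4,Pistol Nutrunner,weighted,NA,NA,2.57,NA
Table 4,Pistol Screw Gunn 1,weighted,NA,NA,4.19,NA
Table 4,Pistol Screw Gunn 2,weighted,NA,NA,5.55,NA
Table 4,Pistol Screw Gunn 3,weighted,NA,NA,2.99,NA
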