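label,x,y,z,subnetwork
vmPFC_1,6,64,3,default mode
aPFC_2,29,57,18,fronto-parietal
aPFC_3,-29,57,10,fronto-parietal
mPFC_4,0,51,32,default mode
aPFC_5,-25,51,27,default mode
vmPFC_6,9,51,16,default mode
vmPFC_7,-6,50,-1,default mode
aPFC_8,27,49,26,cingulo-opercular
vent_aPFC_9,42,48,-3,fronto-parietal
vent_aPFC_10,-43,47,2,fronto-parietal
vmPFC_11,-11,45,17,default mode
vlPFC_12,39,42,16,fronto-parietal
vmPFC_13,8,42,-5,default mode
ACC_14,9,39,20,default mode
vlPFC_15,46,39,-15,default mode
dlPFC_16,40,36,29,fronto-parietal
sup_frontal_17,23,33,47,default mode
vPFC_18,34,32,7,cingulo-opercular
ACC_19,-2,30,27,cingulo-opercular
sup_frontal_20,-16,29,54,default mode
ACC_21,-1,28,40,fronto-parietal
dlPFC_22,46,28,31,fronto-parietal
vPFC_23,-52,28,17,fronto-parietal
dlPFC_24,-44,27,33,fronto-parietal
vFC_25,51,23,8,cingulo-opercular
ant_insula_26,38,21,-1,cingulo-opercular
dACC_27,9,20,34,cingulo-opercular
ant_insula_28,-36,18,2,cingulo-opercular
dFC_29,40,17,40,fronto-parietal
basal_ganglia_30,-6,17,34,cingulo-opercular
mFC_31,0,15,45,cingulo-opercular
frontal_32,58,11,14,sensorimotor
vFC_33,-46,10,14,cingulo-opercular
dFC_34,44,8,34,fronto-parietal
dFC_35,60,8,34,sensorimotor
dFC_36,-42,7,36,fronto-parietal
vFC_37,-55,7,23,sensorimotor
basal_ganglia_38,-20,6,7,cingulo-opercular
basal_ganglia_39,14,6,7,cingulo-opercular
vFC_40,-48,6,1,cingulo-opercular
pre-SMA_41,10,5,51,sensorimotor
vFC_42,43,1,12,sensorimotor
SMA_43,0,-1,52,sensorimotor
mid_insula_44,37,-2,-3,cingulo-opercular
frontal_45,53,-3,32,sensorimotor
precentral_gyrus_46,58,-3,17,sensorimotor
thalamus_47,-12,-3,13,cingulo-opercular
mid_insula_48,-42,-3,11,sensorimotor
precentral_gyrus_49,-44,-6,49,sensorimotor
parietal_50,-26,-8,54,sensorimotor
precentral_gyrus_51,46,-8,24,sensorimotor
precentral_gyrus_52,-54,-9,23,sensorimotor
precentral_gyrus_53,44,-11,38,sensorimotor
parietal_54,-47,-12,36,sensorimotor
mid_insula_55,33,-12,16,sensorimotor
mid_insula_56,-36,-12,15,sensorimotor
thalamus_57,-12,-12,6,cingulo-opercular
thalamus_58,11,-12,6,cingulo-opercular
mid_insula_59,32,-12,2,cingulo-opercular
temporal_60,59,-13,8,sensorimotor
mid_insula_61,-30,-14,1,cingulo-opercular
parietal_62,-38,-15,59,sensorimotor
inf_temporal_63,52,-15,-13,default mode
parietal_64,-47,-18,50,sensorimotor
parietal_65,46,-20,45,sensorimotor
parietal_66,-55,-22,38,sensorimotor
precentral_gyrus_67,-54,-22,22,sensorimotor
temporal_68,-54,-22,9,sensorimotor
parietal_69,41,-23,55,sensorimotor
post_insula_70,42,-24,17,sensorimotor
basal_ganglia_71,11,-24,2,cingulo-opercular
inf_temporal_72,-59,-25,-15,default mode
post_cingulate_73,1,-26,31,default mode
parietal_74,18,-27,62,sensorimotor
parietal_75,-38,-27,60,sensorimotor
post_insula_76,-30,-28,9,cingulo-opercular
parietal_77,-24,-30,64,sensorimotor
temporal_78,51,-30,5,cingulo-opercular
post_parietal_79,-41,-31,48,sensorimotor
post_cingulate_80,-4,-31,-4,cingulo-opercular
fusiform_81,54,-31,-18,cingulo-opercular
temporal_82,-41,-37,16,sensorimotor
temporal_83,-53,-37,13,sensorimotor
fusiform_84,28,-37,-15,default mode
precuneus_85,-3,-38,45,default mode
sup_parietal_86,34,-39,65,sensorimotor
precuneus_87,8,-40,50,cingulo-opercular
IPL_88,-41,-40,42,fronto-parietal
parietal_89,58,-41,20,cingulo-opercular
post_cingulate_90,-8,-41,3,default mode
inf_temporal_91,-61,-41,-2,default mode
occipital_92,-28,-42,-11,default mode
post_cingulate_93,-5,-43,25,default mode
precuneus_94,9,-43,25,default mode
temporal_95,43,-43,8,cingulo-opercular
IPL_96,54,-44,43,fronto-parietal
parietal_97,-55,-44,30,cingulo-opercular
lat_cerebellum_98,-28,-44,-25,cerebellar
post_parietal_99,-35,-46,48,fronto-parietal
sup_temporal_100,42,-46,21,cingulo-opercular
IPL_101,-48,-47,49,fronto-parietal
angular_gyrus_102,-41,-47,29,cingulo-opercular
temporal_103,-59,-47,11,cingulo-opercular
IPL_104,-53,-50,39,fronto-parietal
precuneus_105,5,-50,33,default mode
occipital_106,-18,-50,1,occipital
IPL_107,44,-52,47,fronto-parietal
post_cingulate_108,-5,-52,17,default mode
lat_cerebellum_109,-24,-54,-21,cerebellar
inf_cerebellum_110,-37,-54,-37,cerebellar
post_cingulate_111,10,-55,17,default mode
precuneus_112,-6,-56,29,default mode
lat_cerebellum_113,-34,-57,-24,cerebellar
IPS_114,-32,-58,46,fronto-parietal
post_cingulate_115,-11,-58,17,default mode
IPS_116,32,-59,41,fronto-parietal
angular_gyrus_117,51,-59,34,default mode
occipital_118,-34,-60,-5,occipital
occipital_119,36,-60,-8,occipital
med_cerebellum_120,-6,-60,-15,cerebellar
inf_cerebellum_121,-25,-60,-34,cerebellar
inf_cerebellum_122,32,-61,-31,cerebellar
temporal_123,46,-62,5,occipital
angular_gyrus_124,-48,-63,35,default mode
TPJ_125,-52,-63,15,cingulo-opercular
occipital_126,-44,-63,-7,occipital
med_cerebellum_127,-16,-64,-21,cerebellar
lat_cerebellum_128,21,-64,-22,cerebellar
occipital_129,19,-66,-1,occipital
med_cerebellum_130,1,-66,-24,cerebellar
inf_cerebellum_131,-34,-67,-29,cerebellar
precuneus_132,11,-68,42,default mode
occipital_133,17,-68,20,occipital
IPS_134,-36,-69,40,default mode
occipital_135,39,-71,13,occipital
occipital_136,-9,-72,41,default mode
occipital_137,45,-72,29,default mode
med_cerebellum_138,-11,-72,-14,cerebellar
occipital_139,29,-73,29,occipital
inf_cerebellum_140,33,-73,-30,cerebellar
occipital_141,-2,-75,32,default mode
occipital_142,-29,-75,28,occipital
med_cerebellum_143,5,-75,-11,cerebellar
med_cerebellum_144,14,-75,-21,cerebellar
occipital_145,-16,-76,33,occipital
occipital_146,-42,-76,26,default mode
occipital_147,9,-76,14,occipital
occipital_148,15,-77,32,occipital
occipital_149,20,-78,-2,occipital
inf_cerebellum_150,-21,-79,-33,cerebellar
inf_cerebellum_151,-6,-79,-33,cerebellar
post_occipital_152,-5,-80,9,occipital
post_occipital_153,29,-81,14,occipital
post_occipital_154,33,-81,-2,occipital
inf_cerebellum_155,18,-81,-33,cerebellar
post_occipital_156,-37,-83,-2,occipital
post_occipital_157,-29,-88,8,occipital
post_occipital_158,13,-91,2,occipital
post_occipital_159,27,-91,2,occipital
post_occipital_160,-4,-94,12,occipital
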