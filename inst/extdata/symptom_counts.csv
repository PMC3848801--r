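symptom,group,count,percent
pelvic_pain,malignant,30,50.0
abdominal_pain,malignant,23,38.3
back_pain,malignant,17,28.3
unable_to_eat_normally,malignant,22,36.7
feeling_full_quickly,malignant,22,36.1
indigestion,malignant,15,24.6
nausea_or_vomiting,malignant,11,18.0
weight_loss,malignant,19,31.7
abdominal_bloating,malignant,36,60.0
increased_abdomen_size,malignant,38,63.3
able_to_feel_abdominal_mass,malignant,14,23.3
urinary_urgency,malignant,8,13.3
frequent_urination,malignant,12,20.0
constipation,malignant,2,3.3
diarrhea,malignant,3,5.1
menstrual_irregularity,malignant,1,1.6
bleeding_after_menopause,malignant,6,10.0
pain_during_intercourse,malignant,0,
bleeding_with_intercourse,malignant,0,
fatigue,malignant,20,33.3
leg_swelling,malignant,6,10.0
difficulty_breathing,malignant,9,15.0
pelvic_pain,benign,23,19.7
abdominal_pain,benign,10,8.5
back_pain,benign,10,8.6
unable_to_eat_normally,benign,8,6.8
feeling_full_quickly,benign,11,9.4
indigestion,benign,7,6.0
nausea_or_vomiting,benign,4,3.4
weight_loss,benign,25,21.6
abdominal_bloating,benign,32,27.4
increased_abdomen_size,benign,31,26.7
able_to_feel_abdominal_mass,benign,11,9.4
urinary_urgency,benign,8,6.8
frequent_urination,benign,16,13.7
constipation,benign,2,1.7
diarrhea,benign,1,0.9
menstrual_irregularity,benign,1,0.9
bleeding_after_menopause,benign,1,0.9
pain_during_intercourse,benign,0,
bleeding_with_intercourse,benign,0,
fatigue,benign,16,13.7
leg_swelling,benign,11,9.4
difficulty_breathing,benign,5,4.3
pelvic_pain,control,2,1.3
abdominal_pain,control,0,
back_pain,control,0,
unable_to_eat_normally,control,1,0.7
feeling_full_quickly,control,1,0.7
indigestion,control,1,0.7
nausea_or_vomiting,control,1,0.7
weight_loss,control,11,7.3
abdominal_bloating,control,0,
increased_abdomen_size,control,1,0.7
able_to_feel_abdominal_mass,control,0,
urinary_urgency,control,2,1.3
frequent_urination,control,2,1.3
constipation,control,0,
diarrhea,control,0,
menstrual_irregularity,control,1,0.7
bleeding_after_menopause,control,0,
pain_during_intercourse,control,1,0.7
bleeding_with_intercourse,control,0,
fatigue,control,3,2.0
leg_swelling,control,1,0.7
difficulty_breathing,control,2,1.3
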