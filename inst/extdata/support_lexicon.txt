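# Seed vocabularies for the three social-support categories.
# Informational support: facts, suggestions, guidance (treatments,
# symptoms, clinicians, insurance). Emotional support: empathy,
# encouragement, feelings. Companionship: everyday chat not necessarily
# health-related. One word per line under a [category] header.

[informational]
treatment
treatments
surgery
chemo
chemotherapy
radiation
oncologist
doctor
doctors
physician
hospital
clinic
diagnosis
diagnosed
medication
medications
drug
drugs
dose
scan
scans
mri
biopsy
tumor
tumour
symptom
symptoms
test
tests
results
insurance
trial
trials
therapy
surgeon
prescription
stage
cells
blood
marker
markers
protocol
infusion
port
remission
recurrence
side_effects
clinical_trial
ct_scan
pet_scan
radiation_therapy
blood_test
lymph_nodes

[emotional]
hope
hopeful
love
loved
sorry
pray
prayers
praying
feel
feeling
feelings
scared
afraid
fear
anxious
anxiety
worried
worry
sad
crying
cried
happy
glad
awful
painful
pain
hurts
strength
strong
courage
brave
comfort
comforting
encourage
encouragement
support
caring
care
hugs
bless
blessed
grateful
thankful
depressed
depression
stress
stressful
overwhelmed
relieved

[companionship]
birthday
holiday
holidays
christmas
thanksgiving
weekend
morning
evening
dinner
lunch
breakfast
coffee
tea
recipe
recipes
cooking
baking
garden
gardening
weather
sunshine
rain
snow
walk
walking
dog
dogs
cat
cats
family
kids
grandchildren
grandkids
husband
wife
friends
neighbor
vacation
trip
travel
movie
movies
book
books
music
game
games
fishing
golf
knitting
daily_life
family_members
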