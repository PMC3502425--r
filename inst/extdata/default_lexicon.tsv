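lasix	m
percocet	m
tylenol	m
aspirin	m
lisinopril	m
metoprolol	m
atenolol	m
amlodipine	m
simvastatin	m
atorvastatin	m
pravastatin	m
lovastatin	m
omeprazole	m
pantoprazole	m
ranitidine	m
famotidine	m
metformin	m
glipizide	m
glyburide	m
insulin	m
warfarin	m
coumadin	m
heparin	m
lovenox	m
plavix	m
clopidogrel	m
digoxin	m
diltiazem	m
verapamil	m
nifedipine	m
hydralazine	m
captopril	m
enalapril	m
ramipril	m
losartan	m
valsartan	m
furosemide	m
hydrochlorothiazide	m
spironolactone	m
bumetanide	m
prednisone	m
prednisolone	m
hydrocortisone	m
dexamethasone	m
albuterol	m
ipratropium	m
fluticasone	m
salmeterol	m
montelukast	m
theophylline	m
amoxicillin	m
ampicillin	m
penicillin	m
cephalexin	m
ceftriaxone	m
cefazolin	m
azithromycin	m
erythromycin	m
clarithromycin	m
ciprofloxacin	m
levofloxacin	m
moxifloxacin	m
vancomycin	m
gentamicin	m
clindamycin	m
metronidazole	m
doxycycline	m
trimethoprim	m
nitrofurantoin	m
fluconazole	m
acyclovir	m
oseltamivir	m
morphine	m
oxycodone	m
hydromorphone	m
fentanyl	m
codeine	m
tramadol	m
ibuprofen	m
naproxen	m
ketorolac	m
celecoxib	m
acetaminophen	m
gabapentin	m
pregabalin	m
carbamazepine	m
phenytoin	m
levetiracetam	m
valproate	m
lamotrigine	m
topiramate	m
sertraline	m
fluoxetine	m
paroxetine	m
citalopram	m
escitalopram	m
venlafaxine	m
duloxetine	m
bupropion	m
mirtazapine	m
trazodone	m
amitriptyline	m
nortriptyline	m
lorazepam	m
diazepam	m
alprazolam	m
clonazepam	m
temazepam	m
zolpidem	m
haloperidol	m
risperidone	m
olanzapine	m
quetiapine	m
aripiprazole	m
lithium	m
levothyroxine	m
methimazole	m
propylthiouracil	m
allopurinol	m
colchicine	m
methotrexate	m
hydroxychloroquine	m
azathioprine	m
cyclosporine	m
tacrolimus	m
mycophenolate	m
ondansetron	m
promethazine	m
metoclopramide	m
prochlorperazine	m
loperamide	m
docusate	m
senna	m
bisacodyl	m
lactulose	m
polyethylene glycol	m
magnesium oxide	m
calcium carbonate	m
ferrous sulfate	m
folic acid	m
cyanocobalamin	m
thiamine	m
vitamin d	m
multivitamin	m
potassium chloride	m
sodium bicarbonate	m
nitroglycerin	m
isosorbide	m
isosorbide mononitrate	m
isosorbide dinitrate	m
amiodarone	m
sotalol	m
flecainide	m
dofetilide	m
carvedilol	m
labetalol	m
propranolol	m
nadolol	m
clonidine	m
doxazosin	m
terazosin	m
tamsulosin	m
finasteride	m
sildenafil	m
oxybutynin	m
tolterodine	m
latanoprost	m
timolol	m
brimonidine	m
fluocinonide	m
triamcinolone	m
mupirocin	m
bacitracin	m
nystatin	m
ketoconazole	m
miconazole	m
clotrimazole	m
caltrate plus d	m
caltrate	m
centrum silver	m
fish oil	m
glucosamine	m
os-cal	m
tums	m
maalox	m
mylanta	m
milk of magnesia	m
nexium	m
protonix	m
prilosec	m
zantac	m
pepcid	m
zocor	m
lipitor	m
crestor	m
norvasc	m
toprol	m
lopressor	m
tenormin	m
cozaar	m
diovan	m
altace	m
zestril	m
prinivil	m
glucophage	m
januvia	m
lantus	m
humalog	m
novolog	m
synthroid	m
ambien	m
ativan	m
valium	m
xanax	m
klonopin	m
neurontin	m
lyrica	m
dilantin	m
keppra	m
depakote	m
zoloft	m
prozac	m
paxil	m
celexa	m
lexapro	m
effexor	m
cymbalta	m
wellbutrin	m
remeron	m
desyrel	m
seroquel	m
zyprexa	m
risperdal	m
haldol	m
abilify	m
motrin	m
advil	m
aleve	m
toradol	m
celebrex	m
ultram	m
vicodin	m
dilaudid	m
ms contin	m
oxycontin	m
flexeril	m
baclofen	m
robaxin	m
zofran	m
phenergan	m
reglan	m
compazine	m
imodium	m
colace	m
dulcolax	m
miralax	m
keflex	m
zithromax	m
cipro	m
levaquin	m
augmentin	m
bactrim	m
flagyl	m
diflucan	m
zovirax	m
tamiflu	m
pain	r
dizziness	r
dizzy	r
fever	r
diabetes	r
nausea	r
hypertension	r
anxiety	r
insomnia	r
constipation	r
cough	r
angina	r
rare angina	r
frequent pvcs	r
infection	r
seizures	r
headache	r
depression	r
reflux	r
edema	r
agitation	r
wheezing	r
vomiting	r
diarrhea	r
rash	r
chest pain	r
atrial fibrillation	r
high blood pressure	r
hyperlipidemia	r
gout	r
asthma	r
copd	r
back pain	r
leg swelling	r
shortness of breath	r
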