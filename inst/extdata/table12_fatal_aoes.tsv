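fatal_event	fatal_pt	other_aoe_pts	status	cv_history	cv_risk_factors
Bradycardiac arrest	Cardiac arrest	Cardiac arrest; Dry gangrene; Peripheral ischemia	CML	Congestive heart failure; Hypertension; Impaired diastolic filling pattern; Left atrium enlargement; Mild tricuspid regurgitation; Mitral valve calcification without significant mitral stenosis; Intermittent ventricular tachycardia	Obesity; Diabetes mellitus; Arterial hypertension
Cardiac failure	Cardiac failure	Myocardial infarction; Coronary artery disease; Pulmonary embolism	CML	Pericarditis; Ischemic heart failure	
Intracranial hemorrhage	Hemorrhage intracranial		CML	Aortic stenosis; Calcified mitral annulus	
Worsening of congestive heart failure	Cardiac failure congestive	Myocardial infarction; Deep vein thrombosis	CML	QTc prolongation with nilotinib use; Stent placement; Congestive heart failure; Myocardial infarction; Coronary artery disease; Mitral regurgitation; Trace of tricuspid valve regurgitation	Hyperlipidemia; Arterial hypertension
Superior mesenteric artery occlusion	Mesenteric arterial occlusion	Celiac artery occlusion	ALL	Paroxysmal atrial fibrillation; Thrombophlebitis; Bilateral leg deep vein thrombosis; Cardiac catheterization	Hyperlipidemia; Arterial hypertension
Cardiac arrest	Cardiac arrest	Peripheral vascular disorder	ALL	Greater saphenous vein thrombosis and cellulitis; Aortic valve slightly thickened; Left axis deviation; Left bundle branch block; Hypertension; Mild aortic regurgitation; Mild pulmonic valve regurgitation; Mild to moderate tricuspid regurgitation	Arterial hypertension
Hemorrhagic cerebral infarction	Hemorrhagic cerebral infarction	Cerebral artery stenosis (2 events); Cerebral infarction (2 events)	CML		Diabetes mellitus; Arterial hypertension
Cardiac arrest	Cardiac arrest		CML		
Cardiac arrest	Cardiac arrest		CML	Ischemic heart disease; Angina pectoris; Coronary artery disease	Type 2 diabetes mellitus; Hypertension
Congestive heart failure	Cardiac failure congestive		CML		
Stroke	Cerebrovascular accident	Acute myocardial infarction (2 events)	CML	Ischemic stroke; Ischemic heart disease; Coronary artery disease; Revascularization and coronary stent placement	Diabetes mellitus; Arterial hypertension; Hypercholesterolemia
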