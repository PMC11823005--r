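pt	hlt	hlgt	soc	primary_soc
HEADACHE	Headaches NEC	Headaches	Nervous system disorders	1
HEAD DISCOMFORT	Headaches NEC	Headaches	Nervous system disorders	1
TENSION HEADACHE	Headaches NEC	Headaches	Nervous system disorders	1
SINUS HEADACHE	Headaches NEC	Headaches	Nervous system disorders	1
HEADACHE	Pain and discomfort NEC	General system disorders NEC	General disorders and administration site conditions	0
MIGRAINE	Migraine headaches	Headaches	Nervous system disorders	1
MIGRAINE WITH AURA	Migraine headaches	Headaches	Nervous system disorders	1
MIGRAINE WITHOUT AURA	Migraine headaches	Headaches	Nervous system disorders	1
ANOSMIA	Olfactory nerve disorders	Cranial nerve disorders (excl neoplasms)	Nervous system disorders	1
HYPOSMIA	Olfactory nerve disorders	Cranial nerve disorders (excl neoplasms)	Nervous system disorders	1
PAROSMIA	Olfactory nerve disorders	Cranial nerve disorders (excl neoplasms)	Nervous system disorders	1
HYPOAESTHESIA	Paraesthesias and dysaesthesias	Neurological disorders NEC	Nervous system disorders	1
PARAESTHESIA	Paraesthesias and dysaesthesias	Neurological disorders NEC	Nervous system disorders	1
DYSAESTHESIA	Paraesthesias and dysaesthesias	Neurological disorders NEC	Nervous system disorders	1
ALLODYNIA	Sensory abnormalities NEC	Neurological disorders NEC	Nervous system disorders	1
BURNING SENSATION	Sensory abnormalities NEC	Neurological disorders NEC	Nervous system disorders	1
DIZZINESS	Neurological signs and symptoms NEC	Neurological disorders NEC	Nervous system disorders	1
TREMOR	Tremor (excl congenital)	Movement disorders (incl parkinsonism)	Nervous system disorders	1
ANXIETY	Anxiety symptoms	Anxiety disorders and symptoms	Psychiatric disorders	1
NERVOUSNESS	Anxiety symptoms	Anxiety disorders and symptoms	Psychiatric disorders	1
STRESS	Anxiety symptoms	Anxiety disorders and symptoms	Psychiatric disorders	1
PANIC ATTACK	Panic attacks and disorders	Anxiety disorders and symptoms	Psychiatric disorders	1
PANIC DISORDER	Panic attacks and disorders	Anxiety disorders and symptoms	Psychiatric disorders	1
DEPRESSION	Depressive disorders	Mood disorders and disturbances NEC	Psychiatric disorders	1
DEPRESSED MOOD	Depressive disorders	Mood disorders and disturbances NEC	Psychiatric disorders	1
MAJOR DEPRESSION	Depressive disorders	Mood disorders and disturbances NEC	Psychiatric disorders	1
SUICIDAL IDEATION	Suicidal and self-injurious behaviours NEC	Suicidal and self-injurious behaviour	Psychiatric disorders	1
SUICIDE ATTEMPT	Suicidal and self-injurious behaviours NEC	Suicidal and self-injurious behaviour	Psychiatric disorders	1
COMPLETED SUICIDE	Suicidal and self-injurious behaviours NEC	Suicidal and self-injurious behaviour	Psychiatric disorders	1
SELF-INJURIOUS IDEATION	Suicidal and self-injurious behaviours NEC	Suicidal and self-injurious behaviour	Psychiatric disorders	1
INSOMNIA	Insomnias	Sleep disorders and disturbances	Psychiatric disorders	1
INITIAL INSOMNIA	Insomnias	Sleep disorders and disturbances	Psychiatric disorders	1
MIDDLE INSOMNIA	Insomnias	Sleep disorders and disturbances	Psychiatric disorders	1
NIGHTMARE	Parasomnias	Sleep disorders and disturbances	Psychiatric disorders	1
SLEEP DISORDER	Sleep disorders NEC	Sleep disorders and disturbances	Psychiatric disorders	1
IRRITABILITY	Mood alterations NEC	Mood disorders and disturbances NEC	Psychiatric disorders	1
MOOD SWINGS	Mood alterations NEC	Mood disorders and disturbances NEC	Psychiatric disorders	1
NAUSEA	Nausea and vomiting symptoms	Gastrointestinal signs and symptoms	Gastrointestinal disorders	1
VOMITING	Nausea and vomiting symptoms	Gastrointestinal signs and symptoms	Gastrointestinal disorders	1
DIARRHOEA	Diarrhoea (excl infective)	Gastrointestinal motility and defaecation conditions	Gastrointestinal disorders	1
NAUSEA	General symptoms NEC	General system disorders NEC	General disorders and administration site conditions	0
FATIGUE	Asthenic conditions	General system disorders NEC	General disorders and administration site conditions	1
PYREXIA	Febrile disorders	Body temperature conditions	General disorders and administration site conditions	1
INJECTION SITE PAIN	Injection site reactions	Administration site reactions	General disorders and administration site conditions	1
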