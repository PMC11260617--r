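pt_code	pt_name	hlt_code	hlt_name	soc_code	soc_name
10061428	Decreased appetite	10003018	Appetite disorders	10027433	Metabolism and nutrition disorders
10021654	Increased appetite	10003018	Appetite disorders	10027433	Metabolism and nutrition disorders
10016946	Food craving	10003018	Appetite disorders	10027433	Metabolism and nutrition disorders
10003028	Appetite disorder	10003018	Appetite disorders	10027433	Metabolism and nutrition disorders
10070568	Food aversion	10003018	Appetite disorders	10027433	Metabolism and nutrition disorders
10020710	Hyperphagia	10003018	Appetite disorders	10027433	Metabolism and nutrition disorders
10070571	Food refusal	10003018	Appetite disorders	10027433	Metabolism and nutrition disorders
10059164	Lack of satiety	10003018	Appetite disorders	10027433	Metabolism and nutrition disorders
10012174	Dehydration	10044115	Total fluid volume decreased	10027433	Metabolism and nutrition disorders
10021137	Hypovolaemia	10044115	Total fluid volume decreased	10027433	Metabolism and nutrition disorders
10048851	Fluid intake reduced	10044115	Total fluid volume decreased	10027433	Metabolism and nutrition disorders
10020993	Hypoglycaemia	10021005	Hypoglycaemic conditions NEC	10027433	Metabolism and nutrition disorders
10048803	Hypoglycaemia unawareness	10021005	Hypoglycaemic conditions NEC	10027433	Metabolism and nutrition disorders
10020635	Hyperglycaemia	10018473	Hyperglycaemic conditions NEC	10027433	Metabolism and nutrition disorders
10012607	Diabetes mellitus inadequate control	10018473	Hyperglycaemic conditions NEC	10027433	Metabolism and nutrition disorders
10012671	Diabetic ketoacidosis	10023126	Ketoses	10027433	Metabolism and nutrition disorders
10023379	Ketoacidosis	10023126	Ketoses	10027433	Metabolism and nutrition disorders
10023388	Ketosis	10023126	Ketoses	10027433	Metabolism and nutrition disorders
10074343	Euglycaemic diabetic ketoacidosis	10023126	Ketoses	10027433	Metabolism and nutrition disorders
10057385	Weight loss poor	10047896	Weight and nutrient intake disorders	10027433	Metabolism and nutrition disorders
10026829	Marasmus	10047896	Weight and nutrient intake disorders	10027433	Metabolism and nutrition disorders
10061273	Malnutrition	10047896	Weight and nutrient intake disorders	10027433	Metabolism and nutrition disorders
10028813	Nausea	10028817	Nausea and vomiting symptoms	10017947	Gastrointestinal disorders
10047700	Vomiting	10028817	Nausea and vomiting symptoms	10017947	Gastrointestinal disorders
10012735	Diarrhoea	10012736	Diarrhoea (excl infective)	10017947	Gastrointestinal disorders
10010774	Constipation	10010774	Gastrointestinal atonic and hypomotility disorders	10017947	Gastrointestinal disorders
10000081	Abdominal pain	10000084	Gastrointestinal and abdominal pains	10017947	Gastrointestinal disorders
10013946	Dyspepsia	10018012	Gastrointestinal signs and symptoms NEC	10017947	Gastrointestinal disorders
10033645	Pancreatitis	10033647	Acute and chronic pancreatitis	10017947	Gastrointestinal disorders
10017885	Gastrooesophageal reflux disease	10018012	Gastrointestinal signs and symptoms NEC	10017947	Gastrointestinal disorders
10019211	Headache	10019233	Headaches NEC	10029205	Nervous system disorders
10013573	Dizziness	10027584	Neurological signs and symptoms NEC	10029205	Nervous system disorders
10044565	Tremor	10040927	Tremor (excl congenital)	10029205	Nervous system disorders
10013911	Dysgeusia	10012762	Taste and smell disturbances	10029205	Nervous system disorders
10041349	Somnolence	10027584	Neurological signs and symptoms NEC	10029205	Nervous system disorders
10042772	Syncope	10027584	Neurological signs and symptoms NEC	10029205	Nervous system disorders
10016256	Fatigue	10003550	Asthenic conditions	10018065	General disorders and administration site conditions
10003549	Asthenia	10003550	Asthenic conditions	10018065	General disorders and administration site conditions
10025482	Malaise	10003550	Asthenic conditions	10018065	General disorders and administration site conditions
10037660	Pyrexia	10037660	Febrile disorders	10018065	General disorders and administration site conditions
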