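case_id	sex	pretest_phenotype	pretest_syndromic	suspected_inheritance	onset	provenance
OTO.008	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, diagnosed case
OTO.001	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, diagnosed case
OTO.033	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, diagnosed case
OTO.050	female	Bilateral non-syndromic sensorineural deafness	FALSE	AD/AR	childhood	published case series, diagnosed case
OTO.009	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, diagnosed case
OTO.006	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, diagnosed case
OTO.018	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, diagnosed case
OTO.004	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, diagnosed case
OTO.005	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, diagnosed case
OTO.014	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, diagnosed case
OTO.003	male	Bilateral non-syndromic sensorineural deafness	FALSE	AD	childhood	published case series, diagnosed case
OTO.043	female	Bilateral non-syndromic sensorineural deafness	FALSE	AD	congenital	published case series, diagnosed case
OTO.023	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, diagnosed case
OTO.041	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, diagnosed case
OTO.011	female	Unilateral non-syndromic sensorineural deafness	FALSE	AD	childhood	published case series, diagnosed case
OTO.051	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, diagnosed case
OTO.019	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, diagnosed case
OTO.010	male	CHARGE syndrome	TRUE	AD	congenital	published case series, diagnosed case
OTO.015	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, diagnosed case
OTO.016	male	Bilateral non-syndromic sensorineural deafness	FALSE	AD	childhood	published case series, diagnosed case
OTO.007	male	Alport syndrome	TRUE	AR	childhood	published case series, diagnosed case
OTO.017	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, undiagnosed case
OTO.021	female	Bilateral sensorineural deafness with nystagmus, strabismus, psychomotor delay and autism spectrum disorder	FALSE	AR	congenital	published case series, undiagnosed case
OTO.024	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, undiagnosed case
OTO.025	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, undiagnosed case
OTO.026	male	Unilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, undiagnosed case
OTO.027	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, undiagnosed case
OTO.028	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, undiagnosed case
OTO.029	female	Unilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, undiagnosed case
OTO.030	female	Unilateral sensorineural deafness with connective tissue, digestive and urinary problems and knee hypermobility	FALSE	AR	childhood	published case series, undiagnosed case
OTO.032	female	Unilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, undiagnosed case
OTO.034	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, undiagnosed case
OTO.035	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, undiagnosed case
OTO.038	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR	unknown	published case series, undiagnosed case
OTO.040	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, undiagnosed case
OTO.042	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, undiagnosed case
OTO.044	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, undiagnosed case
OTO.045	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	congenital	published case series, undiagnosed case
OTO.046	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, undiagnosed case
OTO.049	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	adulthood	published case series, undiagnosed case
OTO.052	female	Bilateral sensorineural deafness with auricular lobe grooves, polysyndactyly and hypospadias	FALSE	AR	congenital	published case series, undiagnosed case
OTO.053	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR	childhood	published case series, undiagnosed case
OTO.036	male	Bilateral non-syndromic sensorineural deafness	FALSE	AR/AD	childhood	published case series, undiagnosed case
OTO.039	female	Bilateral non-syndromic sensorineural deafness	FALSE	AR/AD	adulthood	published case series, undiagnosed case
OTO.020	male	Bilateral non-syndromic sensorineural deafness	FALSE	AD	childhood	published case series, undiagnosed case
OTO.022	male	Bilateral non-syndromic sensorineural deafness	FALSE	AD	congenital	published case series, undiagnosed case
OTO.031	male	Bilateral non-syndromic sensorineural deafness	FALSE	AD	childhood	published case series, undiagnosed case
OTO.037	female	Bilateral non-syndromic sensorineural deafness	FALSE	AD	adulthood	published case series, undiagnosed case
OTO.047	female	Bilateral non-syndromic sensorineural deafness	FALSE	AD	childhood	published case series, undiagnosed case
OTO.048	female	Bilateral non-syndromic sensorineural deafness	FALSE	AD	childhood	published case series, undiagnosed case
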