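gene	lnl_one_ratio	lnl_two_ratio	omega_background	omega_foreground	p_published
avpr2aa	-8052.433931	-8050.227062	0.14947	0.19676	0.03565064
calua	-3834.889689	-3830.856495	0.02672	0.05400	0.004509392
cd79a	-5616.687395	-5612.184921	0.45934	0.72436	0.002692497
erp44	-5079.939348	-5077.009609	0.06725	0.10572	0.015493388
maf1b	-2616.210118	-2613.102067	0.02824	0.05596	0.012659353
ppargc1a	-8961.544009	-8957.481434	0.24301	0.34983	0.004365537
rtn4rl2a	-5723.916209	-5720.171689	0.05028	0.08127	0.006207564
tsnax	-4643.99952	-4638.188861	0.09101	0.16458	0.000652002
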