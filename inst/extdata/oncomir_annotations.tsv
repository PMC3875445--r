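feature_id	class	citation
mmu-miR-29b	suppressor	curated literature role
mmu-miR-21	oncomir	curated literature role
mmu-miR-10b	oncomir	curated literature role
mmu-miR-451a	suppressor	curated literature role
mmu-miR-17	oncomir	curated literature role
mmu-miR-18a	oncomir	curated literature role
mmu-miR-145	suppressor	curated literature role
mmu-miR-31	oncomir	curated literature role
mmu-let-7g	suppressor	curated literature role
mmu-let-7a	suppressor	curated literature role
mmu-let-7b	suppressor	curated literature role
mmu-let-7c	suppressor	curated literature role
mmu-let-7d	suppressor	curated literature role
mmu-let-7e	suppressor	curated literature role
mmu-let-7f	suppressor	curated literature role
mmu-let-7i	suppressor	curated literature role
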