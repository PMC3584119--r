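taxon	host_class	foliage_age	foraging_type	tent	pupation_site	overwintering	adult_front	tibia_spine	egg_scale_size	urticating_setae
H_cunea	Angiosperm	young	?	temporary	?	prepupa	smooth	absent	?	absent
L_dispar	Angiosperm	young	?	none	?	egg	smooth	absent	?	absent
O_lunifer	Angiosperm	young	central_place	large	soil	egg	smooth	absent	?	present
T_solitaria	Angiosperm	young	patch_restricted	temporary	litter	egg	smooth	absent	medium	present
T_herculeana	Angiosperm	young	nomadic	none	soil	egg	crested	present	medium	present
T_processionea	Angiosperm	young	central_place	large	tent	egg	smooth	absent	medium	present
T_wilkinsoni	Gymnosperm	mature	central_place	large	soil	larva	crested	present	large	present
T_pityocampa_ENA	Gymnosperm	mature	central_place	large	soil	larva	crested	present	large	present
T_pityocampa	Gymnosperm	mature	central_place	large	soil	larva	crested	present	large	present
T_ispartaensis	Gymnosperm	mature	patch_restricted	temporary	soil	egg	crested	present	medium	present
T_libanotica	Gymnosperm	mature	patch_restricted	temporary	soil	egg	crested	present	medium	present
T_bonjeani	Gymnosperm	mature	patch_restricted	temporary	soil	egg	crested	present	medium	present
T_pinivora	Gymnosperm	mature	patch_restricted	temporary	soil	egg	crested	present	medium	present
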