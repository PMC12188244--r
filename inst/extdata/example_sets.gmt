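actin_cytoskeleton_organization	synthetic example set	g00001	g00002	g00003	g00004	g00005	g00006	g00007	g00008	g00009	g00010	g00011	g00012	g00013	g00014	g00015	g00016	g00017	g00018	g00019	g00020	g00021	g00022
regulation_of_membrane_potential	synthetic example set	g00031	g00032	g00033	g00034	g00035	g00036	g00037	g00038	g00039	g00040	g00041	g00042	g00043	g00044	g00045	g00046	g00047	g00048	g00049	g00050
tiny_set_below_size_filter	synthetic example set	g00061	g00062	g00063
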