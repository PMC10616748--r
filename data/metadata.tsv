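sample_id	group	vitd	arm
S001	case	insufficient	treatment
S002	case	insufficient	treatment
S003	case	insufficient	treatment
S004	case	sufficient	placebo
S005	case	insufficient	placebo
S006	case	sufficient	placebo
S007	case	sufficient	treatment
S008	case	insufficient	placebo
S009	case	insufficient	placebo
S010	case	insufficient	treatment
S011	case	insufficient	placebo
S012	case	insufficient	placebo
S013	case	insufficient	treatment
S014	case	insufficient	placebo
S015	case	insufficient	placebo
S016	case	insufficient	treatment
S017	case	insufficient	placebo
S018	case	sufficient	placebo
S019	case	insufficient	treatment
S020	case	insufficient	treatment
S021	case	sufficient	treatment
S022	case	insufficient	treatment
S023	case	insufficient	placebo
S024	case	insufficient	treatment
S025	case	insufficient	placebo
S026	case	insufficient	placebo
S027	case	insufficient	placebo
S028	case	insufficient	placebo
S029	case	insufficient	placebo
S030	case	insufficient	treatment
S031	case	insufficient	placebo
S032	case	insufficient	treatment
S033	case	insufficient	placebo
S034	case	insufficient	placebo
S035	case	insufficient	treatment
S036	case	insufficient	placebo
S037	case	insufficient	treatment
S038	case	insufficient	treatment
S039	case	insufficient	treatment
S040	case	insufficient	placebo
S041	case	insufficient	treatment
S042	case	insufficient	placebo
S043	case	insufficient	placebo
S044	case	insufficient	treatment
S045	case	insufficient	treatment
S046	case	insufficient	placebo
S047	case	insufficient	treatment
S048	control	insufficient	treatment
S049	control	sufficient	treatment
S050	control	insufficient	placebo
S051	control	insufficient	placebo
S052	control	sufficient	treatment
S053	control	insufficient	placebo
S054	control	insufficient	placebo
S055	control	insufficient	placebo
S056	control	insufficient	placebo
S057	control	insufficient	treatment
S058	control	insufficient	placebo
S059	control	insufficient	placebo
S060	control	insufficient	placebo
S061	control	sufficient	treatment
S062	control	insufficient	treatment
S063	control	insufficient	placebo
S064	control	insufficient	treatment
S065	control	insufficient	treatment
S066	control	insufficient	treatment
S067	control	insufficient	treatment
S068	control	sufficient	treatment
S069	control	insufficient	placebo
S070	control	sufficient	treatment
S071	control	insufficient	placebo
S072	control	sufficient	placebo
S073	control	insufficient	treatment
S074	control	insufficient	placebo
S075	control	insufficient	placebo
S076	control	sufficient	placebo
S077	control	sufficient	placebo
S078	control	insufficient	placebo
S079	control	sufficient	treatment
S080	control	sufficient	treatment
S081	control	insufficient	treatment
S082	control	sufficient	treatment
S083	control	insufficient	treatment
S084	control	insufficient	treatment
S085	control	sufficient	treatment
S086	control	insufficient	placebo
S087	control	sufficient	treatment
S088	control	insufficient	placebo
S089	control	insufficient	treatment
S090	control	insufficient	placebo
S091	control	insufficient	treatment
S092	control	insufficient	placebo
S093	control	insufficient	treatment
S094	control	sufficient	placebo
S095	control	sufficient	treatment
S096	control	sufficient	placebo
S097	control	insufficient	placebo
S098	control	insufficient	placebo
S099	control	sufficient	placebo
S100	control	insufficient	treatment
S101	control	insufficient	placebo
S102	control	insufficient	placebo
S103	control	insufficient	treatment
S104	control	sufficient	treatment
S105	control	insufficient	placebo
S106	control	insufficient	placebo
S107	control	insufficient	placebo
S108	control	insufficient	placebo
S109	control	sufficient	treatment
S110	control	insufficient	placebo
S111	control	sufficient	placebo
S112	control	sufficient	treatment
S113	control	insufficient	treatment
S114	control	insufficient	treatment
S115	control	insufficient	treatment
S116	control	insufficient	placebo
S117	control	sufficient	treatment
S118	control	insufficient	placebo
S119	control	insufficient	placebo
S120	control	insufficient	treatment
S121	control	sufficient	treatment
S122	control	insufficient	treatment
S123	control	insufficient	treatment
S124	control	insufficient	treatment
S125	control	sufficient	treatment
S126	control	insufficient	placebo
S127	control	insufficient	treatment
S128	control	insufficient	treatment
S129	control	insufficient	treatment
S130	control	insufficient	treatment
S131	control	insufficient	treatment
S132	control	insufficient	treatment
S133	control	insufficient	treatment
S134	control	insufficient	placebo
S135	control	sufficient	placebo
S136	control	insufficient	treatment
S137	control	insufficient	treatment
S138	control	insufficient	placebo
S139	control	sufficient	treatment
S140	control	insufficient	treatment
S141	control	insufficient	placebo
S142	control	insufficient	treatment
S143	control	insufficient	treatment
S144	control	insufficient	placebo
S145	control	sufficient	placebo
S146	control	insufficient	placebo
S147	control	insufficient	placebo
S148	control	sufficient	placebo
S149	control	insufficient	placebo
S150	control	sufficient	treatment
S151	control	insufficient	treatment
S152	control	insufficient	treatment
S153	control	insufficient	treatment
S154	control	insufficient	placebo
S155	control	insufficient	placebo
S156	control	insufficient	placebo
S157	control	insufficient	placebo
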