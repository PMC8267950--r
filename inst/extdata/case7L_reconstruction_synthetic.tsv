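nucleus_id	COX2	DBC2	MYC	CCND1	CDH1	TP53	HER2	ZNF217	CCP4	CCP10
n1	2	1	3	2	1	2	2	2	2	2
n2	2	1	3	2	1	2	2	2	2	2
n3	2	1	3	2	1	2	2	2	2	2
n4	2	1	3	2	1	2	2	2	2	2
n5	2	1	3	2	1	2	2	2	2	2
n6	2	1	3	2	1	2	2	2	2	2
n7	2	1	3	2	1	2	2	2	2	2
n8	2	1	3	2	1	2	2	2	2	2
n9	2	1	3	2	1	2	2	2	2	2
n10	2	1	3	2	1	2	2	2	2	2
n11	2	1	3	2	1	2	2	2	2	2
n12	2	1	3	2	1	2	2	2	2	2
n13	2	1	3	2	1	2	2	2	2	2
n14	2	1	3	2	1	2	2	2	2	2
n15	2	1	3	2	1	2	2	2	2	2
n16	2	1	3	2	1	2	2	2	2	2
n17	2	1	3	2	1	2	2	2	2	2
n18	2	1	3	2	1	2	2	2	2	2
n19	2	1	3	2	1	2	2	2	2	2
n20	2	1	3	2	1	2	2	2	2	2
n21	2	1	3	2	1	2	2	2	2	2
n22	2	1	3	2	1	2	2	2	2	2
n23	2	1	3	2	1	2	2	2	2	2
n24	2	1	3	2	1	2	2	2	2	2
n25	2	1	3	2	1	2	2	2	2	2
n26	2	1	3	2	1	2	2	2	2	2
n27	2	1	3	2	1	2	2	2	2	2
n28	2	1	3	2	1	2	2	2	2	2
n29	2	1	3	2	1	2	2	2	2	2
n30	2	1	3	2	1	2	2	2	2	2
n31	2	1	3	2	1	2	2	2	2	2
n32	2	1	3	2	1	2	2	2	2	2
n33	2	1	3	2	1	2	2	2	2	2
n34	2	1	3	2	1	2	2	2	2	2
n35	2	1	3	2	1	2	2	2	2	2
n36	2	1	3	2	1	2	2	2	2	2
n37	2	1	3	2	1	2	2	2	2	2
n38	2	1	3	2	1	2	2	2	2	2
n39	2	1	3	2	1	2	2	2	2	2
n40	2	1	3	2	1	2	2	2	2	2
n41	2	1	3	2	1	2	2	2	2	2
n42	2	1	3	2	1	2	2	2	2	2
n43	2	1	3	2	1	2	2	2	2	2
n44	2	1	3	2	1	2	2	2	2	2
n45	2	1	3	2	1	2	2	2	2	2
n46	2	1	3	2	1	2	2	2	2	2
n47	2	1	3	2	1	2	2	2	2	2
n48	2	1	3	2	1	2	2	2	2	2
n49	2	1	3	2	1	2	2	2	2	2
n50	2	1	3	2	1	2	2	2	2	2
n51	2	1	3	2	1	2	2	2	2	2
n52	2	1	3	2	1	2	2	2	2	2
n53	2	1	3	2	1	2	2	2	2	2
n54	2	1	3	2	1	2	2	2	2	2
n55	2	1	3	2	1	2	2	2	2	2
n56	2	1	3	2	1	2	2	2	2	2
n57	2	1	3	2	1	2	2	2	2	2
n58	2	1	3	2	1	2	2	2	2	2
n59	2	1	3	2	1	2	2	2	2	2
n60	2	1	3	2	1	2	2	2	2	2
n61	2	1	3	2	1	2	2	2	2	2
n62	2	1	3	2	1	2	2	2	2	2
n63	2	1	3	2	1	2	2	2	2	2
n64	2	1	3	2	1	2	2	2	2	2
n65	2	1	3	2	1	2	2	2	2	2
n66	2	1	3	2	1	2	2	2	2	2
n67	2	1	3	2	1	2	2	2	2	2
n68	2	1	3	2	1	2	2	2	2	2
n69	2	1	3	2	1	2	2	2	2	2
n70	2	1	3	2	1	2	2	2	2	2
n71	2	1	3	2	1	2	2	2	2	2
n72	2	1	3	2	1	2	2	2	2	2
n73	2	1	3	2	1	2	2	2	2	2
n74	2	1	3	2	1	2	2	2	2	2
n75	2	1	3	2	1	2	2	2	2	2
n76	2	1	3	2	1	2	2	2	2	2
n77	2	1	3	2	1	2	2	2	2	2
n78	2	1	3	2	1	2	2	2	2	2
n79	2	1	3	2	1	2	2	2	2	2
n80	2	1	3	2	1	2	2	2	2	2
n81	2	1	3	2	1	2	2	2	2	2
n82	2	1	3	2	1	2	2	2	2	2
n83	2	1	3	2	1	2	2	2	2	2
n84	2	1	3	2	1	2	2	2	2	2
n85	2	1	3	2	1	2	2	2	2	2
n86	2	1	3	2	1	2	2	2	2	2
n87	2	1	3	2	1	2	2	2	2	2
n88	2	1	3	2	1	2	2	2	2	2
n89	2	1	3	2	1	2	2	2	2	2
n90	2	1	3	2	1	2	2	2	2	2
n91	2	1	3	2	1	2	2	2	2	2
n92	2	1	3	2	1	2	2	2	2	2
n93	2	1	3	2	1	2	2	2	2	2
n94	2	1	3	2	1	2	2	2	2	2
n95	2	1	3	2	1	2	2	2	2	2
n96	2	1	3	2	1	2	2	2	2	2
n97	2	1	3	2	1	2	2	2	2	2
n98	2	1	3	2	1	2	2	2	2	2
n99	2	1	3	2	1	2	2	2	2	2
n100	2	1	3	2	1	2	2	2	2	2
n101	2	1	3	2	1	2	2	2	2	2
n102	2	1	3	2	1	2	2	2	2	2
n103	2	1	3	2	1	2	2	2	2	2
n104	2	1	3	2	1	2	2	2	2	2
n105	2	1	3	2	1	2	2	2	2	2
n106	2	1	3	2	1	2	2	2	2	2
n107	2	1	3	2	1	2	2	2	2	2
n108	2	1	3	2	1	2	2	2	2	2
n109	2	1	3	2	1	2	2	2	2	2
n110	2	1	3	2	1	2	2	2	2	2
n111	2	1	3	2	1	2	2	2	2	2
n112	2	1	3	2	1	2	2	2	2	2
n113	2	1	3	2	1	2	2	2	2	2
n114	2	1	3	2	1	2	2	2	2	2
n115	2	1	3	2	1	2	2	2	2	2
n116	2	1	3	2	1	2	2	2	2	2
n117	2	1	3	2	1	2	2	2	2	2
n118	2	1	3	2	1	2	2	2	2	2
n119	2	1	3	2	1	2	2	2	2	2
n120	2	1	3	2	1	2	2	2	2	2
n121	2	1	3	2	1	2	2	2	2	2
n122	2	1	3	2	1	2	2	2	2	2
n123	2	1	3	2	1	2	2	2	2	2
n124	2	1	3	2	1	2	2	2	2	2
n125	2	1	3	2	1	2	2	2	2	2
n126	2	1	3	2	1	2	2	2	2	2
n127	2	1	3	2	1	2	2	2	2	2
n128	2	1	3	2	1	2	2	2	2	2
n129	2	1	3	2	1	2	2	2	2	2
n130	2	1	3	2	1	2	2	2	2	2
n131	2	1	3	2	1	2	2	2	2	2
n132	2	1	3	2	1	2	2	2	2	2
n133	2	1	3	2	1	2	2	2	2	2
n134	2	1	3	2	1	2	2	2	2	2
n135	2	1	3	2	1	2	2	2	2	2
n136	2	1	3	2	1	2	2	2	2	2
n137	2	1	3	2	1	2	2	2	2	2
n138	2	1	3	2	1	2	2	2	2	2
n139	2	1	3	2	1	2	2	2	2	2
n140	2	1	3	2	1	2	2	2	2	2
n141	2	1	3	2	1	2	2	2	2	2
n142	2	1	3	2	1	2	2	2	2	2
n143	2	1	3	2	1	2	2	2	2	2
n144	2	1	3	2	1	2	2	2	2	2
n145	2	1	3	2	1	2	2	2	2	2
n146	2	1	3	2	1	2	2	2	2	2
n147	2	1	3	2	1	2	2	2	2	2
n148	2	1	3	2	1	2	2	2	2	2
n149	2	1	3	2	1	2	2	2	2	2
n150	2	1	3	2	1	2	2	2	2	2
n151	2	1	3	2	1	2	2	2	2	2
n152	2	1	3	2	1	2	2	2	2	2
n153	2	1	3	2	1	2	2	2	2	2
n154	2	1	3	2	1	2	2	2	2	2
n155	2	1	3	2	1	2	2	2	2	2
n156	2	1	3	2	1	2	2	2	2	2
n157	2	1	3	2	1	2	2	2	2	2
n158	2	1	3	2	1	2	2	2	2	2
n159	2	1	3	2	1	2	2	2	2	2
n160	2	1	3	2	1	2	2	2	2	2
n161	2	1	3	2	1	2	2	2	2	2
n162	2	1	3	2	1	2	2	2	2	2
n163	2	1	3	2	1	2	2	2	2	2
n164	2	1	3	2	1	2	2	2	2	2
n165	2	1	3	2	1	2	2	2	2	2
n166	2	1	3	2	1	2	2	2	2	2
n167	2	1	3	2	1	2	2	2	2	2
n168	2	1	3	2	1	2	2	2	2	2
n169	2	1	3	2	1	2	2	2	2	2
n170	2	1	3	2	1	2	2	2	2	2
n171	2	1	3	2	1	2	2	2	2	2
n172	2	1	3	2	1	2	2	2	2	2
n173	2	1	3	2	1	2	2	2	2	2
n174	2	1	3	2	1	2	2	2	2	2
n175	2	1	3	2	1	2	2	2	2	2
n176	2	1	3	2	1	2	2	2	2	2
n177	2	1	3	2	1	2	2	2	2	2
n178	2	1	3	2	1	2	2	2	2	2
n179	2	1	3	2	1	2	2	2	2	2
n180	2	1	3	2	1	2	2	2	2	2
n181	2	1	3	2	1	2	2	2	2	2
n182	2	1	3	2	1	2	2	2	2	2
n183	2	1	3	2	1	2	2	2	2	2
n184	2	1	3	2	1	2	2	2	2	2
n185	2	1	3	2	1	2	2	2	2	2
n186	2	1	3	2	1	2	2	2	2	2
n187	2	1	3	2	1	2	2	2	2	2
n188	2	1	3	2	1	2	2	2	2	2
n189	2	1	3	2	1	2	2	2	2	2
n190	2	1	3	2	1	2	2	2	2	2
n191	2	1	3	2	1	2	2	2	2	2
n192	2	1	3	2	1	2	2	2	2	2
n193	2	1	3	2	1	2	2	2	2	2
n194	2	1	3	2	1	2	2	2	2	2
n195	2	1	3	2	1	2	2	2	2	2
n196	2	1	3	2	1	2	2	2	2	2
n197	2	1	3	2	1	2	2	2	2	2
n198	2	1	3	2	1	2	2	2	2	2
n199	2	1	3	2	1	2	2	2	2	2
n200	2	1	3	2	1	2	2	2	2	2
n201	2	1	3	2	1	2	2	2	2	2
n202	2	1	3	2	1	2	2	2	2	2
n203	2	1	3	2	1	2	2	2	2	2
n204	2	1	3	2	1	2	2	2	2	2
n205	2	1	3	2	1	2	2	2	2	2
n206	2	1	3	2	1	2	2	2	2	2
n207	2	1	3	2	1	2	2	2	2	2
n208	2	1	3	2	1	2	2	2	2	2
n209	2	1	3	2	1	2	2	2	2	2
n210	2	1	3	2	1	2	2	2	2	2
n211	2	1	3	2	1	2	2	2	2	2
n212	2	1	3	2	1	2	2	2	2	2
n213	2	1	3	2	1	2	2	2	2	2
n214	2	1	3	2	1	2	2	2	2	2
n215	2	1	3	2	1	2	2	2	2	2
n216	2	1	3	2	1	2	2	2	2	2
n217	2	1	3	2	1	2	2	2	2	2
n218	2	1	4	2	1	2	2	2	2	2
n219	2	1	4	2	1	2	2	2	2	2
n220	2	1	4	2	1	2	2	2	2	2
n221	2	1	4	2	1	2	2	2	2	2
n222	2	1	4	2	1	2	2	2	2	2
n223	2	1	4	2	1	2	2	2	2	2
n224	2	1	4	2	1	2	2	2	2	2
n225	2	1	4	2	1	2	2	2	2	2
n226	2	1	4	2	1	2	2	2	2	2
n227	2	1	4	2	1	2	2	2	2	2
n228	2	1	4	2	1	2	2	2	2	2
n229	2	1	4	2	1	2	2	2	2	2
n230	2	1	4	2	1	2	2	2	2	2
n231	2	1	4	2	1	2	2	2	2	2
n232	2	1	4	2	1	2	2	2	2	2
n233	2	1	4	2	1	2	2	2	2	2
n234	2	1	4	2	1	2	2	2	2	2
n235	2	1	4	2	1	2	2	2	2	2
n236	2	1	4	2	1	2	2	2	2	2
n237	2	1	4	2	1	2	2	2	2	2
n238	2	1	4	2	1	2	2	2	2	2
n239	2	1	4	2	1	2	2	2	2	2
n240	2	1	4	2	1	2	2	2	2	2
n241	2	1	4	2	1	2	2	2	2	2
n242	2	1	4	2	1	2	2	2	2	2
n243	2	1	4	2	1	2	2	2	2	2
n244	2	1	4	2	1	2	2	2	2	2
n245	2	1	4	2	1	2	2	2	2	2
n246	2	1	4	2	1	2	2	2	2	2
n247	2	1	3	2	1	2	2	3	2	2
n248	2	1	3	2	1	2	2	3	2	2
n249	2	2	3	2	1	2	2	2	2	2
n250	2	1	3	2	2	2	2	2	2	2
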