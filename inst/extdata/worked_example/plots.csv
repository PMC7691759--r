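"trial_id","series","site_id","genotype_id","is_check","replicate","sub_block","yield_t_ha"
"A1",1,"A1","CHK1",TRUE,1,1,2.5
"A1",1,"A1","CHK2",TRUE,1,1,2.3
"A1",1,"A1","L11",FALSE,1,1,2.6
"A1",1,"A1","L12",FALSE,1,1,2.4
"A1",1,"A1","L13",FALSE,1,1,2.2
"A1",1,"A1","CHK1",TRUE,2,1,2.5
"A1",1,"A1","CHK2",TRUE,2,1,2.3
"A1",1,"A1","L11",FALSE,2,1,2.6
"A1",1,"A1","L12",FALSE,2,1,2.4
"A1",1,"A1","L13",FALSE,2,1,2.2
"A2",1,"A2","CHK1",TRUE,1,1,4.7
"A2",1,"A2","CHK2",TRUE,1,1,4.5
"A2",1,"A2","L11",FALSE,1,1,4.8
"A2",1,"A2","L12",FALSE,1,1,4.6
"A2",1,"A2","L13",FALSE,1,1,4.4
"A2",1,"A2","CHK1",TRUE,2,1,4.7
"A2",1,"A2","CHK2",TRUE,2,1,4.5
"A2",1,"A2","L11",FALSE,2,1,4.8
"A2",1,"A2","L12",FALSE,2,1,4.6
"A2",1,"A2","L13",FALSE,2,1,4.4
"A3",1,"A3","CHK1",TRUE,1,1,6.6
"A3",1,"A3","CHK2",TRUE,1,1,6.4
"A3",1,"A3","L11",FALSE,1,1,6.7
"A3",1,"A3","L12",FALSE,1,1,6.5
"A3",1,"A3","L13",FALSE,1,1,6.3
"A3",1,"A3","CHK1",TRUE,2,1,6.6
"A3",1,"A3","CHK2",TRUE,2,1,6.4
"A3",1,"A3","L11",FALSE,2,1,6.7
"A3",1,"A3","L12",FALSE,2,1,6.5
"A3",1,"A3","L13",FALSE,2,1,6.3
"B1",2,"B1","CHK1",TRUE,1,1,2.5
"B1",2,"B1","CHK2",TRUE,1,1,2.3
"B1",2,"B1","L21",FALSE,1,1,2.7
"B1",2,"B1","L22",FALSE,1,1,2.5
"B1",2,"B1","L23",FALSE,1,1,2.3
"B1",2,"B1","CHK1",TRUE,2,1,2.5
"B1",2,"B1","CHK2",TRUE,2,1,2.3
"B1",2,"B1","L21",FALSE,2,1,2.7
"B1",2,"B1","L22",FALSE,2,1,2.5
"B1",2,"B1","L23",FALSE,2,1,2.3
"B2",2,"B2","CHK1",TRUE,1,1,4.7
"B2",2,"B2","CHK2",TRUE,1,1,4.5
"B2",2,"B2","L21",FALSE,1,1,4.9
"B2",2,"B2","L22",FALSE,1,1,4.7
"B2",2,"B2","L23",FALSE,1,1,4.5
"B2",2,"B2","CHK1",TRUE,2,1,4.7
"B2",2,"B2","CHK2",TRUE,2,1,4.5
"B2",2,"B2","L21",FALSE,2,1,4.9
"B2",2,"B2","L22",FALSE,2,1,4.7
"B2",2,"B2","L23",FALSE,2,1,4.5
"B3",2,"B3","CHK1",TRUE,1,1,6.6
"B3",2,"B3","CHK2",TRUE,1,1,6.4
"B3",2,"B3","L21",FALSE,1,1,6.8
"B3",2,"B3","L22",FALSE,1,1,6.6
"B3",2,"B3","L23",FALSE,1,1,6.4
"B3",2,"B3","CHK1",TRUE,2,1,6.6
"B3",2,"B3","CHK2",TRUE,2,1,6.4
"B3",2,"B3","L21",FALSE,2,1,6.8
"B3",2,"B3","L22",FALSE,2,1,6.6
"B3",2,"B3","L23",FALSE,2,1,6.4
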