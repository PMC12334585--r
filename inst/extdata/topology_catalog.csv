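name,edge_template,n_edges,n_nodes,sequential,recurrence
Line,A>B,1,2,TRUE,FALSE
Ring,"A>B,B>A",2,2,TRUE,TRUE
Chain,"A>B,B>C",2,3,TRUE,FALSE
Triple_line,"A>B,B>A,A>B",3,2,TRUE,TRUE
Star_pre,"A>B,B>A,A>C",3,3,TRUE,TRUE
Triad,"A>B,B>C,C>A",3,3,TRUE,TRUE
Star_pos,"A>B,B>C,C>B",3,3,TRUE,TRUE
Triple_chain,"A>B,B>C,C>D",3,4,TRUE,FALSE
Four_times_line,"A>B,B>A,A>B,B>A",4,2,TRUE,TRUE
Seq4_ABABC,"A>B,B>A,A>B,B>C",4,3,TRUE,TRUE
Seq4_ABACA,"A>B,B>A,A>C,C>A",4,3,TRUE,TRUE
Seq4_ABACB,"A>B,B>A,A>C,C>B",4,3,TRUE,TRUE
Seq4_ABACD,"A>B,B>A,A>C,C>D",4,4,TRUE,TRUE
Seq4_ABCAB,"A>B,B>C,C>A,A>B",4,3,TRUE,TRUE
Seq4_ABCAC,"A>B,B>C,C>A,A>C",4,3,TRUE,TRUE
Seq4_ABCAD,"A>B,B>C,C>A,A>D",4,4,TRUE,TRUE
Seq4_ABCBA,"A>B,B>C,C>B,B>A",4,3,TRUE,TRUE
Seq4_ABCBC,"A>B,B>C,C>B,B>C",4,3,TRUE,TRUE
Seq4_ABCBD,"A>B,B>C,C>B,B>D",4,4,TRUE,TRUE
Seq4_ABCDA,"A>B,B>C,C>D,D>A",4,4,TRUE,TRUE
Seq4_ABCDB,"A>B,B>C,C>D,D>B",4,4,TRUE,TRUE
Seq4_ABCDC,"A>B,B>C,C>D,D>C",4,4,TRUE,TRUE
Ring_n,"A>B,A>B",2,2,FALSE,TRUE
Chain_n1,"A>B,A>C",2,3,FALSE,TRUE
Chain_n2,"A>B,C>B",2,3,FALSE,TRUE
Chain_n3,"A>B,C>A",2,3,FALSE,TRUE
Triple_line_n1,"A>B,A>B,B>A",3,2,FALSE,TRUE
Triple_line_n2,"A>B,B>A,B>A",3,2,FALSE,TRUE
Star_pos_n1,"A>B,B>A,C>A",3,3,FALSE,TRUE
Star_pos_n2,"A>B,C>B,B>C",3,3,FALSE,TRUE
Triad_n,"A>B,C>A,B>C",3,3,FALSE,TRUE
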