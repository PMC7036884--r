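id,territory,name,enrollment_total,enrollment_grade9
S01,Krahô,Escola Municipal Antonio Carlos Jobim,599,99
S02,Xambioá,Escola Municipal AntonioG. De Carvalho Filho,618,70
S03,Apinajé,Escola Municipal Anne Frank,838,80
S04,Xambioá,Escola Municipal Darcy Ribeiro,476,117
S05,Apinajé,Escola Municipal Henrique Talone Pinheiro,794,80
S06,Xambioá,Escola Municipal de Tempo Integral Vinícius de Moraes,483,81
S07,Kanela,Escola Municipal Beatriz Rodrigues da Silva,897,157
S08,Kanela,Escola Municipal Mestre Pacifico S. Campos,431,74
S09,Kanela,Escola Municipal Luiz Gonzaga,264,65
S10,Kanela,Escola Municipal Tempo Integral Padre Josimo M. Tavares,1087,116
S11,Apinajé,Escola Municipal Tempo Integral Daniel Batista,386,29
S12,Apinajé,Escola Municipal Tempo Integral Monsenhor Pedro P. Piagem,466,35
S13,Javaé,Escola Municipal Jorge Amado,568,159
S14,Javaé,Escola Municipal Maria Rosa De Castro Sales,703,79
S15,Krahô,Escola Municipal Professora Savia F. Jacome,558,71
S16,Javaé,Escola Municipal de Tempo Integral Caroline C. C. Da Silva,1187,72
S17,Karajá,Escola Municipal Aurelio Buarque De Holanda,776,115
S18,Xerente,Escola Municipal Maria Julia Amorim Rodrigues,694,176
S19,Karajá,Escola Municipal Thiago Barbosa,896,104
S20,Xerente,Escola Municipal de Tempo Integral Euridice F. De Mello,1088,68
S21,Xerente,Escola Municipal de Tempo Integral Margarida Gonçalves,1028,62
S22,Pankararu,Escola Municipal Crispim Pereira Alencar,565,33
S23,Apinajé,Escola Municipal de Tempo Integral Aprigio T. De Matos,235,15
S24,Pankararu,Escola Municipal de Tempo Integral Joao Beltrao,217,21
S25,Pankararu,Escola Municipal de Tempo Integral Luiz Nunes De Oliveira,249,22
S26,Pankararu,Escola Municipal de Tempo Integral Sueli Pereira A. Reche,218,14
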