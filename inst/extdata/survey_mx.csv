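survey_id,label,text,yes_pct,no_pct
Mx,a,"Thanks to scientific and technological advances, the Earth's natural resources will be inexhaustible.",33,63
Mx,b,"Science and technology can sort out any problem.",21,76
Mx,c,"Science and technology cannot really play a role in improving the environment.",15,81
Mx,d,"Science should have no limits to what it is able to investigate.",70,17
Mx,e,"We depend too much on science and not enough on faith.",16,84
Mx,f,"Some numbers are especially lucky for some people.",34,64
Mx,g,"Scientists should be allowed to experiment on animals like dogs and monkeys if this can help sort out human health problems.",57,41
Mx,h,"The benefits of science are greater than any harmful effects it may have.",69,23
Mx,i,"Because of their knowledge, scientists have a power that makes them dangerous.",57,39
Mx,j,"Science makes our ways of life change too fast.",83,14
Mx,k,"The application of science and new technologies will make people's work more interesting.",81,15
Mx,l,"Compared with research carried out and funded by each Member State, collaborative research across the country is in the national interest.",94,3
Mx,m,"Even if it brings no immediate benefits, scientific research which adds to knowledge should be supported by Government.",88,9
Mx,n,"Thanks to science and technology, there will be more opportunities for future generations.",88,9
Mx,o,"A scientific discovery is in itself neither 'good' nor 'bad', it is only the way the discovery is used which matters.",91,6
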